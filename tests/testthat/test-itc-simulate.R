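# Forward calorimetric models: oracle equivalence, conservation laws,
# limiting behaviour.

# Per-injection heats for the tight-binder titration (Kb = 2.9e7,
# n = 1.06, dH = -6.9 at the default design), computed once with the
# bisection mass-balance oracle (helper-oracles.R) and frozen.
FROZEN_ONE_SITE <- c(
  -6.895151481, -6.89419513, -6.892787606, -6.890894638, -6.88846899,
  -6.885444079, -6.881723622, -6.877164168, -6.871544375, -6.86450814,
  -6.855452746, -6.843291883, -6.825904621, -6.798690864, -6.750126093,
  -6.644667888, -6.333466701, -5.031714243, -2.042220971, -0.5652515912)

test_that("one-site simulator matches the frozen bisection-oracle vector", {
  tg <- simulate_one_site(titration_design(), Kb = 2.9e7, n = 1.06,
                          dH = -6.9)
  expect_equal(tg$heats_norm, FROZEN_ONE_SITE, tolerance = 1e-8)
  # sigmoidal exothermic curve saturating near zero heat
  expect_true(all(tg$heats_norm < 0))
  expect_lt(abs(tg$heats_norm[20]), 0.1 * abs(tg$heats_norm[1]))
})

test_that("closed-form occupancy equals bisection mass balance on random draws", {
  set.seed(101)
  n_draw <- 1000
  Kb <- 10^stats::runif(n_draw, 3, 9)
  sites <- 10^stats::runif(n_draw, -6, -3)
  ligand <- 10^stats::runif(n_draw, -6, -3)
  dev <- vapply(seq_len(n_draw), function(i) {
    qf <- quadratic_bound_ligand(Kb[i], sites[i], ligand[i])
    bf <- oracle_bound_ligand(Kb[i], sites[i], ligand[i])
    abs(qf - bf) / max(bf, 1e-300)
  }, numeric(1))
  expect_lt(max(dev), 1e-8)
})

test_that("simulator agrees with the full bisection titration across parameters", {
  set.seed(202)
  d <- titration_design()
  for (i in 1:15) {
    Kb <- 10^stats::runif(1, 4, 8)
    n <- stats::runif(1, 0.4, 2)
    dH <- stats::runif(1, -12, -2)
    sim <- simulate_one_site(d, Kb, n, dH)$heats_norm
    orc <- oracle_one_site_heats(d, Kb, n, dH)
    expect_equal(sim, orc, tolerance = 1e-8)
  }
})

test_that("mass conservation: cell contents never exceed moles delivered", {
  d <- titration_design()
  dV <- d$cumulative_volumes
  X <- d$syringe_conc * (dV / d$cell_volume) * (1 - dV / (2 * d$cell_volume))
  delivered <- d$syringe_conc * dV
  expect_true(all(X * d$cell_volume <= delivered * (1 + 1e-10)))
  # cell species only ever decreases from its initial amount
  M <- d$cell_conc * (1 - dV / (2 * d$cell_volume)) /
    (1 + dV / (2 * d$cell_volume))
  expect_true(all(diff(M) < 0) && all(M < d$cell_conc))
})

test_that("one-site limits: zero enthalpy, sign law, saturation of total heat", {
  d <- titration_design()
  expect_equal(simulate_one_site(d, 1e7, 1, 0)$heats_norm, rep(0, 20))
  for (dH in c(-6.9, 3.2)) {
    h <- simulate_one_site(d, 2.9e7, 1.06, dH)$heats_norm
    expect_true(all(sign(h) == sign(dH)))
  }
  # saturating design (concentrated syringe, molar ratio >> 3, c ~ 1537):
  # cumulative heat approaches n * M0 * V0 * dH
  ds <- titration_design(syringe_conc = 4e-3)
  tot <- sum(simulate_one_site(ds, 2.9e7, 1.06, -6.9)$heats_kcal)
  expect_equal(tot, 1.06 * 50e-6 * 1.4482e-3 * -6.9, tolerance = 0.01)
})

test_that("dilution simulator: monomer fraction closed form and limits", {
  d <- titration_design(cell_conc = 0)
  # at C = K_dim the monomer fraction is 1/2
  expect_equal(oracle_monomer_fraction(1.6e-3, 1.6e-3), 0.5)
  tg <- simulate_dilution_dimer(d, K_dim = 1.6e-3, dH_dim = -66)
  # endothermic, decaying series (sign opposite to dH_dim)
  expect_true(all(tg$heats_norm > 0))
  expect_true(all(diff(tg$heats_norm) < 0))
  # fully monomeric limit: no dimer, no heat
  expect_equal(simulate_dilution_dimer(d, K_dim = 1e6, dH_dim = -66)$heats_norm,
               rep(0, 20), tolerance = 1e-6)
  # dimer conservation per injection: heat never exceeds the enthalpy
  # content of the dimers present plus those injected
  D_syr <- (400e-6 - oracle_monomer_fraction(400e-6, 1.6e-3) * 400e-6) / 2
  max_heat <- 66 * D_syr * 10e-6
  expect_true(all(tg$heats_kcal <= max_heat * (1 + 1e-10)))
})

test_that("simulators validate their domains", {
  d <- titration_design()
  d0 <- titration_design(cell_conc = 0)
  expect_error(simulate_one_site(d0, 1e6, 1, -5), "simulate_dilution_dimer")
  expect_error(simulate_one_site(d, -1e6, 1, -5), "Kb")
  expect_error(simulate_one_site(d, 1e6, -1, -5), "n")
  expect_error(simulate_dilution_dimer(d, 1e-3, -66), "cell_conc = 0")
  expect_error(simulate_dilution_dimer(d0, -1e-3, -66), "K_dim")
  expect_error(titration_design(injection_volumes = numeric()), "non-empty")
  expect_error(titration_design(cell_volume = -1), "cell_volume")
})

test_that("raw and normalized heats interconvert exactly", {
  tg <- simulate_one_site(titration_design(), 2.9e7, 1.06, -6.9)
  moles <- tg$design$syringe_conc * tg$design$injection_volumes
  expect_equal(tg$heats_norm * moles * 1e9, tg$heats_ucal)
  rt <- thermogram(tg$design, tg$heats_ucal)
  expect_equal(rt$heats_norm, tg$heats_norm)
})

test_that("blank subtraction removes an additive dilution offset exactly", {
  d <- titration_design()
  pure <- simulate_one_site(d, 2.9e7, 1.06, -6.9)
  offset <- thermogram(d, rep(1, 20))                 # 1 ucal per injection
  contaminated <- thermogram(d, pure$heats_ucal + 1)
  corrected <- subtract_dilution(contaminated, offset)
  expect_equal(corrected$heats_ucal, pure$heats_ucal)
  expect_equal(corrected$heats_norm, pure$heats_norm)
  # identical runs cancel; zero blank is a no-op
  expect_equal(subtract_dilution(pure, pure)$heats_ucal, rep(0, 20))
  zero <- thermogram(d, rep(0, 20))
  expect_equal(subtract_dilution(pure, zero)$heats_ucal, pure$heats_ucal)
  # schedule mismatch names the offending injections
  d2 <- titration_design(injection_volumes = c(rep(10e-6, 19), 12e-6))
  blank2 <- thermogram(d2, rep(1, 20))
  expect_error(subtract_dilution(pure, blank2), "20")
})
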