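# Parameter recovery for both calorimetric fits.

test_that("one-site fit recovers noiseless truths to well under 0.1%", {
  d <- titration_design()
  truths <- list(c(Kb = 2.0e6, n = 1.01, dH = -7.1),
                 c(Kb = 2.9e7, n = 1.06, dH = -6.9),
                 c(Kb = 3.9e5, n = 0.50, dH = -8.3),
                 c(Kb = 1.1e4, n = 1.00, dH = -8.4))
  for (tr in truths) {
    fit <- fit_one_site(simulate_one_site(d, tr["Kb"], tr["n"], tr["dH"]))
    expect_identical(fit$outcome, "ok")
    expect_equal(fit$thermo$Kb, unname(tr["Kb"]), tolerance = 1e-3)
    expect_equal(fit$thermo$n, unname(tr["n"]), tolerance = 1e-3)
    expect_equal(fit$thermo$dH, unname(tr["dH"]), tolerance = 1e-3)
    expect_equal(fit$c_value, unname(tr["Kb"] * tr["n"]) * 50e-6,
                 tolerance = 1e-3)
    # derived decomposition carried at the design temperature
    expect_equal(fit$thermo$dG, delta_g_from_kb(fit$thermo$Kb, 303.15))
  }
})

test_that("flat or heat-free input yields the no-binding outcome", {
  d <- titration_design()
  zero <- thermogram(d, rep(0, 20))
  fit <- fit_one_site(zero)
  expect_identical(fit$outcome, "no_binding")
  expect_null(fit$thermo)
  # pure noise, no signal
  set.seed(3)
  noise_only <- thermogram(d, stats::rnorm(20, sd = 0.5))
  expect_identical(fit_one_site(noise_only)$outcome, "no_binding")
})

test_that("dilution-model fit recovers noiseless truth to well under 0.1%", {
  d <- titration_design(cell_conc = 0)
  fit <- fit_dilution_dimer(simulate_dilution_dimer(d, 1.6e-3, -66))
  expect_identical(fit$outcome, "ok")
  expect_equal(fit$K_dim, 1.6e-3, tolerance = 1e-3)
  expect_equal(fit$dH_dim, -66, tolerance = 1e-3)
  # zero heats: unidentifiable, flagged
  expect_identical(fit_dilution_dimer(thermogram(d, rep(0, 20)))$outcome,
                   "degenerate")
})

test_that("dilution fit is robust to 2% noise across seeded replicates", {
  d <- titration_design(cell_conc = 0)
  ref <- simulate_dilution_dimer(d, 1.6e-3, -66)
  sigma <- 0.02 * abs(ref$heats_ucal[1])
  set.seed(5)
  ks <- replicate(100, {
    tg <- simulate_dilution_dimer(d, 1.6e-3, -66, noise_sd = sigma)
    fit_dilution_dimer(tg)$K_dim
  })
  expect_lt(abs(stats::median(ks) - 1.6e-3) / 1.6e-3, 0.10)
})

test_that("fits reject the wrong experiment geometry", {
  d <- titration_design()
  d0 <- titration_design(cell_conc = 0)
  tg <- simulate_one_site(d, 1e6, 1, -5)
  expect_error(fit_dilution_dimer(tg), "cell_conc = 0")
  tg0 <- simulate_dilution_dimer(d0, 1.6e-3, -66)
  expect_error(fit_one_site(tg0), "fit_dilution_dimer")
  short <- titration_design(injection_volumes = rep(10e-6, 4))
  expect_error(fit_one_site(simulate_one_site(short, 1e6, 1, -5)),
               "at least 5")
})

test_that("Kb uncertainty degrades at very high c under fixed noise", {
  # two-point comparison: c ~ 10 (Kb = 2e5) vs c ~ 1450 (Kb = 2.9e7) at
  # a fixed 4-ucal injection noise, seeded Monte-Carlo spread of ln Kb
  mc_sd <- function(Kb) {
    d <- titration_design()
    vals <- replicate(40, {
      tg <- simulate_one_site(d, Kb, 1.0, -6.9, noise_sd = 4)
      f <- suppressWarnings(fit_one_site(tg))
      if (f$outcome == "ok") log(f$thermo$Kb) else NA_real_
    })
    stats::sd(vals, na.rm = TRUE)
  }
  set.seed(11)
  sd_low_c <- mc_sd(2e5)
  sd_high_c <- mc_sd(2.9e7)
  expect_gt(sd_high_c, sd_low_c)
})
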