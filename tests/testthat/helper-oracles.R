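# Independent oracles used to cross-check the analysis code.
# These deliberately avoid the closed forms used inside the package.

# Bound-ligand concentration for one class of sites by bisection on the
# free-ligand concentration: mass balance
#   X_total = X_free + Kb * X_free * S_total / (1 + Kb * X_free)
# solved to a relative tolerance of 1e-12.
oracle_bound_ligand <- function(Kb, site_total, ligand_total) {
  if (ligand_total <= 0 || site_total <= 0) return(0)
  f <- function(xf) xf + Kb * xf * site_total / (1 + Kb * xf) - ligand_total
  lo <- 0
  hi <- ligand_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-12 * ligand_total) break
  }
  ligand_total - (lo + hi) / 2
}

# Full titration simulated with the bisection solver; shares only the
# textbook perfusion-cell dilution bookkeeping with the implementation.
oracle_one_site_heats <- function(design, Kb, n, dH) {
  V0 <- design$cell_volume
  dv <- design$injection_volumes
  dV <- cumsum(dv)
  M <- design$cell_conc * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0))
  X <- design$syringe_conc * (dV / V0) * (1 - dV / (2 * V0))
  bound <- mapply(function(m, x) oracle_bound_ligand(Kb, n * m, x), M, X)
  Q <- bound * dH * V0
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2
  q / (design$syringe_conc * dv)   # kcal per mole of injectant
}

# Closed-form quadratic occupancy (re-derived here): bound ligand from
# the positive root of Kb*b^2 - (1 + Kb*(S+X))*b + Kb*S*X = 0.
quadratic_bound_ligand <- function(Kb, site_total, ligand_total) {
  b <- 1 + Kb * (site_total + ligand_total)
  (b - sqrt(b^2 - 4 * Kb^2 * site_total * ligand_total)) / (2 * Kb)
}

# Analytic distance distribution of a uniform sphere of radius R:
# p(r) proportional to r^2 (1 - 3u/4 + u^3/16), u = r/R <= 2.
oracle_sphere_pr <- function(r, R) {
  u <- r / R
  p <- r^2 * (1 - 0.75 * u + u^3 / 16)
  p[u > 2 | u < 0] <- 0
  p
}

# Monomer fraction for 2M <=> D at total monomer-equivalent C, from the
# closed form of the dissociation quadratic.
oracle_monomer_fraction <- function(C, K) {
  (-K + sqrt(K^2 + 8 * K * C)) / (4 * C)
}
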