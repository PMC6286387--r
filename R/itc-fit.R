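## Nonlinear least-squares estimation for the two calorimetric models.
##
## Both fits run in log space for the equilibrium constant (the natural
## scale for constants spanning decades) with Levenberg-Marquardt and a
## small multi-start grid, which keeps them robust at high c-values
## where the transition is nearly a step.

LNKB_LOWER <- log(1e2)
LNKB_UPPER <- log(1e12)

#' Fit the one-site binding model to a thermogram
#'
#' Minimizes the sum of squared residuals between observed normalized
#' heats and [simulate_one_site()] over (ln Kb, n, dH).  The heat of
#' dilution must already be subtracted (see [subtract_dilution()]).
#'
#' A run with no usable signal — fitted |dH| below three times the
#' residual RMS, or Kb pinned at the lower search bound — is reported as
#' `outcome = "no_binding"` with no thermodynamic parameters, the
#' analogue of a "not determined" table entry.
#'
#' @param tg a [thermogram()] with at least 5 injections.
#' @param initial_guess optional named list with any of `Kb`, `n`, `dH`
#'   to override the data-driven starting point.
#' @return Object of class `one_site_fit`: `outcome` ("ok",
#'   "no_binding" or "not_converged"), `thermo` (a [binding_thermo()],
#'   or NULL), `residual_rms` (kcal/mol injectant), `c_value`
#'   (Kb * n * cell_conc), `covariance` (3x3, over ln Kb, n, dH) and
#'   `fitted` heats.
#' @examples
#' tg <- simulate_one_site(titration_design(), Kb = 2.9e7, n = 1.06, dH = -6.9)
#' fit <- fit_one_site(tg)
#' fit$thermo$Kb / 2.9e7   # ~= 1
#' @export
fit_one_site <- function(tg, initial_guess = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  design <- tg$design
  if (length(design$injection_volumes) < 5)
    stop("one-site fit requires at least 5 injections")
  if (design$cell_conc <= 0)
    stop("cell_conc is 0: fit_dilution_dimer() is the model for dilution runs")
  y <- tg$heats_norm

  if (all(abs(y) < 1e-12))
    return(no_binding_result(tg, reason = "all heats are zero"))

  guess <- one_site_start(tg)
  if (!is.null(initial_guess$Kb)) guess$lnKb <- log(initial_guess$Kb)
  if (!is.null(initial_guess$n))  guess$n <- initial_guess$n
  if (!is.null(initial_guess$dH)) guess$dH <- initial_guess$dH

  resid_fun <- function(p) {
    sim <- simulate_one_site(design, Kb = exp(p[1]), n = p[2], dH = p[3])
    sim$heats_norm - y
  }

  starts <- list(c(guess$lnKb, guess$n, guess$dH))
  for (lk in log(c(1e4, 1e6, 1e8)))
    starts <- c(starts, list(c(lk, guess$n, guess$dH)))

  best <- NULL
  for (p0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun,
      lower = c(LNKB_LOWER, 1e-3, -Inf),
      upper = c(LNKB_UPPER, 10, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(outcome = "not_converged", thermo = NULL,
                          residual_rms = NA_real_, c_value = NA_real_,
                          covariance = NULL, fitted = NULL, design = design),
                     class = "one_site_fit"))

  p <- best$par
  rms <- sqrt(best$deviance / length(y))
  Kb <- exp(p[1]); n <- p[2]; dH <- p[3]

  ## no-binding rule: enthalpy or the whole fitted curve lost in the
  ## residual noise, Kb pinned at the lower search bound, or the binding
  ## model failing to explain at least half the heat variance (a large
  ## |dH| on a vanishing isotherm is the classic noise-chasing fit)
  signal <- max(abs(y - best$fvec))
  r2 <- 1 - best$deviance / max(sum((y - mean(y))^2), 1e-300)
  if (abs(dH) < 3 * rms || signal < 3 * rms || r2 < 0.5 ||
      p[1] <= LNKB_LOWER + 1e-8)
    return(no_binding_result(tg, reason = "signal indistinguishable from noise",
                             residual_rms = rms))

  covar <- tryCatch({
    dof <- max(length(y) - 3, 1)
    solve(best$hessian) * 2 * best$deviance / (2 * dof)
  }, error = function(e) NULL)

  structure(list(
    outcome = "ok",
    thermo = binding_thermo(Kb, n, dH, celsius_to_kelvin(design$temperature_c)),
    residual_rms = rms,
    c_value = Kb * n * design$cell_conc,
    covariance = covar,
    fitted = y - best$fvec,
    design = design), class = "one_site_fit")
}

no_binding_result <- function(tg, reason, residual_rms = 0) {
  structure(list(outcome = "no_binding", thermo = NULL,
                 residual_rms = residual_rms, c_value = NA_real_,
                 covariance = NULL, fitted = NULL, design = tg$design,
                 reason = reason), class = "one_site_fit")
}

## Data-driven starting point: dH from the early plateau, n from the
## molar ratio at the steepest descent of the curve, Kb from the width
## of the transition in cell-concentration units.
one_site_start <- function(tg) {
  design <- tg$design
  y <- tg$heats_norm
  dil <- cell_dilution(design)
  mr <- dil$X / dil$M                       # molar ratio per injection
  dH0 <- y[1]
  steep <- which.max(abs(diff(y)))
  n0 <- max(min((mr[steep] + mr[steep + 1]) / 2, 5), 0.1)
  span <- abs(y - dH0 / 2)
  width <- max(diff(range(mr[span < abs(dH0) / 4])), 0.2)
  Kb0 <- 1 / (design$cell_conc * width)
  list(lnKb = min(max(log(Kb0), LNKB_LOWER + 1), LNKB_UPPER - 1),
       n = n0, dH = dH0)
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("One-site titration fit:", x$outcome, "\n")
  if (x$outcome == "ok") {
    print(x$thermo)
    cat(sprintf("  c-value = %.0f, residual RMS = %.3g kcal/mol\n",
                x$c_value, x$residual_rms))
  } else if (!is.null(x$reason)) cat(" ", x$reason, "\n")
  invisible(x)
}

#' Fit the monomer-dimer dissociation model to a dilution thermogram
#'
#' Least-squares estimation of the dimer dissociation constant and the
#' enthalpy of dimerization from a dilution-into-buffer injection
#' series, using [simulate_dilution_dimer()] as the forward model with
#' `K_dim` searched in log space.
#'
#' @param tg a [thermogram()] whose design has `cell_conc = 0`.
#' @return Object of class `dimer_fit`: `outcome`, `K_dim` (mol/L),
#'   `dH_dim` (kcal/mol dimer), `residual_rms`, `covariance`, `fitted`.
#' @examples
#' d <- titration_design(cell_conc = 0)
#' tg <- simulate_dilution_dimer(d, 1.6e-3, -66)
#' fit <- fit_dilution_dimer(tg)
#' c(fit$K_dim * 1e3, fit$dH_dim)   # ~ 1.6 mM, -66 kcal/mol
#' @export
fit_dilution_dimer <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  design <- tg$design
  if (design$cell_conc != 0)
    stop("dilution fit requires a protein-free cell (cell_conc = 0)")
  y <- tg$heats_norm

  if (all(abs(y) < 1e-12))
    return(structure(list(outcome = "degenerate", K_dim = NA_real_,
                          dH_dim = NA_real_, residual_rms = 0,
                          covariance = NULL, fitted = NULL,
                          reason = "zero heats: dH_dim unidentifiable"),
                     class = "dimer_fit"))

  resid_fun <- function(p) {
    sim <- simulate_dilution_dimer(design, K_dim = exp(p[1]), dH_dim = p[2])
    sim$heats_norm - y
  }

  ## dH0 sign: endothermic dilution (positive heats) implies exothermic
  ## dimerization (negative dH_dim).
  dH0 <- -sign(y[1]) * max(abs(y)) * 4
  best <- NULL
  for (lk in log(c(1e-4, 1e-3, 1e-2))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(lk, dH0), fn = resid_fun,
      lower = c(log(1e-9), -Inf), upper = c(log(10), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(outcome = "not_converged", K_dim = NA_real_,
                          dH_dim = NA_real_, residual_rms = NA_real_,
                          covariance = NULL, fitted = NULL),
                     class = "dimer_fit"))

  rms <- sqrt(best$deviance / length(y))
  covar <- tryCatch({
    dof <- max(length(y) - 2, 1)
    solve(best$hessian) * best$deviance / dof
  }, error = function(e) NULL)
  structure(list(outcome = "ok", K_dim = exp(best$par[1]),
                 dH_dim = best$par[2], residual_rms = rms,
                 covariance = covar, fitted = y - best$fvec,
                 design = design), class = "dimer_fit")
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat("Monomer-dimer dilution fit:", x$outcome, "\n")
  if (x$outcome == "ok")
    cat(sprintf("  K_dim = %.3g mM, dH_dim = %.1f kcal/mol dimer, RMS = %.3g\n",
                x$K_dim * 1e3, x$dH_dim, x$residual_rms))
  invisible(x)
}
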