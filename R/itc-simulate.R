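## Forward models for perfusion-cell titration calorimetry.
##
## Both simulators use the classic displaced-volume bookkeeping of a
## constant-volume perfusion cell: injected liquid displaces an equal
## volume of well-mixed cell contents, so after cumulative dispensed
## volume dV the cell species is diluted by
##   M = M0 (1 - dV/2V0) / (1 + dV/2V0)
## and the accumulated titrant concentration is
##   X = X0 (dV/V0) (1 - dV/2V0).

#' Titration design for an injection calorimeter
#'
#' Geometry and concentrations of an injection series.  Defaults match a
#' typical VP-ITC style experiment: twenty 10 ul injections of a 400 uM
#' titrant into a 1.4482 ml cell holding 50 uM of the binding partner at
#' 30 degrees C.
#'
#' @param cell_volume active cell volume, litres.
#' @param injection_volumes per-injection dispensed volumes, litres.
#' @param syringe_conc total titrant concentration in the syringe, mol/L.
#' @param cell_conc total concentration of the cell species, mol/L.  Use
#'   0 for a dilution-into-buffer experiment.
#' @param temperature_c cell temperature, degrees Celsius.
#' @return Object of class `titration_design`.
#' @examples
#' d <- titration_design()
#' sum(d$injection_volumes) * 1e6  # 200 ul dispensed in total
#' @export
titration_design <- function(cell_volume = 1.4482e-3,
                             injection_volumes = rep(10e-6, 20),
                             syringe_conc = 400e-6,
                             cell_conc = 50e-6,
                             temperature_c = 30) {
  if (!length(injection_volumes))
    stop("`injection_volumes` must be non-empty")
  if (any(injection_volumes <= 0))
    stop("`injection_volumes` must all be positive")
  if (cell_volume <= 0) stop("`cell_volume` must be positive")
  if (syringe_conc < 0) stop("`syringe_conc` must be >= 0")
  if (cell_conc < 0) stop("`cell_conc` must be >= 0")
  out <- list(cell_volume = cell_volume,
              injection_volumes = as.numeric(injection_volumes),
              cumulative_volumes = cumsum(as.numeric(injection_volumes)),
              syringe_conc = syringe_conc,
              cell_conc = cell_conc,
              temperature_c = temperature_c)
  class(out) <- "titration_design"
  out
}

#' @export
print.titration_design <- function(x, ...) {
  cat(sprintf(
    "Titration design: %d injections (%.1f ul total) of %.0f uM into %.4f ml of %.0f uM at %.0f C\n",
    length(x$injection_volumes), sum(x$injection_volumes) * 1e6,
    x$syringe_conc * 1e6, x$cell_volume * 1e3, x$cell_conc * 1e6,
    x$temperature_c))
  invisible(x)
}

same_schedule <- function(a, b, tol = 1e-12) {
  length(a$injection_volumes) == length(b$injection_volumes) &&
    all(abs(a$injection_volumes - b$injection_volumes) <= tol) &&
    abs(a$cell_volume - b$cell_volume) <= tol
}

## Diluted cell-species and accumulated titrant concentrations after
## cumulative dispensed volume dV.
cell_dilution <- function(design) {
  dV <- design$cumulative_volumes
  V0 <- design$cell_volume
  list(M = design$cell_conc * (1 - dV / (2 * V0)) / (1 + dV / (2 * V0)),
       X = design$syringe_conc * (dV / V0) * (1 - dV / (2 * V0)))
}

new_thermogram <- function(design, heats_kcal, dilution_reference = NULL) {
  moles_inj <- design$syringe_conc * design$injection_volumes
  out <- list(design = design,
              heats_kcal = as.numeric(heats_kcal),          # kcal per injection
              heats_ucal = as.numeric(heats_kcal) * 1e9,    # microcalories
              heats_norm = as.numeric(heats_kcal) / moles_inj, # kcal/mol injectant
              dilution_reference = dilution_reference)
  class(out) <- "thermogram"
  out
}

#' Integrated heats of a titration, with design metadata
#'
#' Constructor used by the simulators and file readers.  Heats are kept
#' in two interconvertible representations: raw per-injection heat
#' (kcal, and microcalories) and heats normalized per mole of injectant
#' (kcal/mol), the form usually fitted and plotted.
#'
#' @param design a [titration_design()].
#' @param heats_ucal per-injection integrated heats, microcalories.
#' @param dilution_reference optional matching blank-run `thermogram`.
#' @return Object of class `thermogram` with fields `design`,
#'   `heats_kcal`, `heats_ucal`, `heats_norm`, `dilution_reference`.
#' @export
thermogram <- function(design, heats_ucal, dilution_reference = NULL) {
  if (length(heats_ucal) != length(design$injection_volumes))
    stop("`heats_ucal` length must equal the number of injections")
  new_thermogram(design, as.numeric(heats_ucal) * 1e-9, dilution_reference)
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram: %d injections, heats %.3g .. %.3g kcal/mol injectant\n",
              length(x$heats_norm), x$heats_norm[1],
              x$heats_norm[length(x$heats_norm)]))
  invisible(x)
}

#' Simulate a one-site association titration
#'
#' Closed-form per-injection heats for the single-class-of-sites binding
#' isotherm in a perfusion cell.  With r = X/(nM) and s = 1/(n Kb M) the
#' cumulative heat content after injection i is
#' \deqn{Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + r + s -
#'   \sqrt{(1 + r + s)^2 - 4r}\right]}
#' and the measured heat of injection i corrects for material carried
#' out with the displaced volume:
#' \deqn{q_i = Q_i - Q_{i-1} + \frac{dv_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}.}
#'
#' @param design a [titration_design()] with `cell_conc > 0`.
#' @param Kb association constant, M^-1.
#' @param n stoichiometry.
#' @param dH enthalpy change, kcal per mole of injectant bound.
#' @param noise_sd optional Gaussian noise s.d. on the raw heats,
#'   microcalories.  Uses the current RNG state; seed upstream.
#' @return A [thermogram()].
#' @examples
#' tg <- simulate_one_site(titration_design(), Kb = 2.9e7, n = 1.06, dH = -6.9)
#' round(tg$heats_norm[1:3], 2)
#' @export
simulate_one_site <- function(design, Kb, n, dH, noise_sd = 0) {
  stopifnot(inherits(design, "titration_design"))
  if (design$cell_conc <= 0)
    stop("cell_conc is 0: this is a dilution design; use simulate_dilution_dimer()")
  if (Kb <= 0) stop("`Kb` must be positive")
  if (n <= 0) stop("`n` must be positive")
  dil <- cell_dilution(design)
  M <- dil$M
  X <- dil$X
  V0 <- design$cell_volume
  r <- X / (n * M)
  s <- 1 / (n * Kb * M)
  Q <- (n * M * dH * V0 / 2) * (1 + r + s - sqrt((1 + r + s)^2 - 4 * r))
  Qprev <- c(0, Q[-length(Q)])
  dv <- design$injection_volumes
  q <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2
  if (noise_sd > 0)
    q <- q + stats::rnorm(length(q), sd = noise_sd) * 1e-9
  new_thermogram(design, q)
}

## Monomer concentration at total monomer-equivalent concentration C for
## the equilibrium 2M <=> D with dissociation constant K = [M]^2/[D].
## Algebraically (-K + sqrt(K^2 + 8KC))/4, rewritten as
## 2C/(1 + sqrt(1 + 8C/K)) which stays accurate when K >> C.
dimer_monomer_conc <- function(C, K_dim) {
  ifelse(C <= 0, 0, 2 * C / (1 + sqrt(1 + 8 * C / K_dim)))
}

## Dimer concentration at total monomer-equivalent concentration C.
dimer_conc <- function(C, K_dim) {
  (C - dimer_monomer_conc(C, K_dim)) / 2
}

#' Simulate dilution of a self-dimerizing protein into buffer
#'
#' Models the endothermic signal of injecting a concentrated
#' monomer-dimer mixture into protein-free buffer.  The equilibrium
#' 2M <=> D with dissociation constant `K_dim = [M]^2/[D]` is solved in
#' the syringe and, after every injection, in the cell; the heat is the
#' enthalpy of the net dimer loss:
#' \deqn{q_i = -\Delta H_{dim} (n_D^{before} + n_D^{injected} - n_D^{after}).}
#' With exothermic dimer formation (`dH_dim < 0`) dilution absorbs heat,
#' and successive injections absorb less as the cell concentration grows.
#'
#' @param design a [titration_design()] with `cell_conc = 0`;
#'   `syringe_conc` is the total monomer-equivalent concentration.
#' @param K_dim dimer dissociation constant, mol/L.
#' @param dH_dim enthalpy of dimerization, kcal per mole of dimer formed.
#' @param noise_sd optional Gaussian noise s.d. on raw heats, microcalories.
#' @return A [thermogram()] (normalized per mole of monomer-equivalent
#'   injectant).
#' @examples
#' d <- titration_design(cell_conc = 0)
#' tg <- simulate_dilution_dimer(d, K_dim = 1.6e-3, dH_dim = -66)
#' all(tg$heats_norm > 0)          # endothermic
#' all(diff(tg$heats_norm) < 0)    # decaying
#' @export
simulate_dilution_dimer <- function(design, K_dim, dH_dim, noise_sd = 0) {
  stopifnot(inherits(design, "titration_design"))
  if (design$cell_conc != 0)
    stop("dilution model requires a protein-free cell (cell_conc = 0)")
  if (K_dim <= 0) stop("`K_dim` must be positive")
  V0 <- design$cell_volume
  dv <- design$injection_volumes
  C_total <- cell_dilution(design)$X   # monomer-equivalent conc after each injection
  D_cell <- dimer_conc(C_total, K_dim) # dimer conc at each post-injection equilibrium
  D_prev <- c(0, D_cell[-length(D_cell)])
  D_syr <- dimer_conc(design$syringe_conc, K_dim)
  q <- -dH_dim * (D_prev * V0 + D_syr * dv - D_cell * V0)
  if (noise_sd > 0)
    q <- q + stats::rnorm(length(q), sd = noise_sd) * 1e-9
  new_thermogram(design, q)
}

#' Subtract a blank (heat-of-dilution) run from a sample run
#'
#' @param sample,blank [thermogram()] objects sharing the same injection
#'   schedule and cell volume.
#' @return A corrected `thermogram` (raw heats differenced, then
#'   renormalized).
#' @export
subtract_dilution <- function(sample, blank) {
  stopifnot(inherits(sample, "thermogram"), inherits(blank, "thermogram"))
  if (!same_schedule(sample$design, blank$design)) {
    ds <- sample$design$injection_volumes
    db <- blank$design$injection_volumes
    n <- max(length(ds), length(db))
    length(ds) <- n; length(db) <- n
    bad <- which(is.na(ds) | is.na(db) | abs(ds - db) > 1e-12)
    stop("injection schedules differ at injection(s): ",
         paste(bad, collapse = ", "))
  }
  new_thermogram(sample$design, sample$heats_kcal - blank$heats_kcal)
}
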