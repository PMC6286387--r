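## Size-exclusion calibration and oligomeric-state estimation.

#' Fit a size-exclusion calibration curve
#'
#' Least-squares line of log10(MW) on elution volume, the standard SEC
#' calibration.  Larger species elute earlier, so the slope must be
#' negative.
#'
#' @param standards data.frame with columns `elution_volume` (ml) and
#'   `mw` (kDa); at least three standards with distinct volumes.
#' @return Object of class `sec_calibration`: `slope`, `intercept`
#'   (log10-kDa scale), `r_squared`, `volume_range`, `standards`.
#' @examples
#' std <- data.frame(elution_volume = c(10, 12, 14, 16),
#'                   mw = c(440, 158, 44, 13.7))
#' cal <- fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("elution_volume", "mw") %in% names(standards)))
  if (nrow(standards) < 3)
    stop("calibration needs at least 3 standards")
  if (anyDuplicated(standards$elution_volume))
    stop("duplicate elution volumes in standards")
  if (any(standards$mw <= 0))
    stop("standard molecular weights must be positive")
  ord <- order(standards$elution_volume)
  if (any(diff(standards$mw[ord]) >= 0))
    stop("standards are non-monotone: MW must decrease with elution volume")
  fit <- stats::lm(log10(mw) ~ elution_volume, data = standards)
  ## exactly collinear standards are legitimate (synthetic calibrants);
  ## drop the perfect-fit note summary() emits for them
  r2 <- withCallingHandlers(summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(slope = stats::coef(fit)[[2]],
                 intercept = stats::coef(fit)[[1]],
                 r_squared = r2,
                 volume_range = range(standards$elution_volume),
                 standards = standards[ord, ]),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration: log10(MW/kDa) = %.4f %+.4f * V, r2 = %.4f, V in [%.2f, %.2f] ml\n",
              x$intercept, x$slope, x$r_squared,
              x$volume_range[1], x$volume_range[2]))
  invisible(x)
}

#' Apparent molecular weight at an elution volume
#'
#' @param curve a [fit_calibration()] result.
#' @param volume elution volume, ml.
#' @return Apparent MW, kDa.
#' @export
apparent_mw <- function(curve, volume) {
  stopifnot(inherits(curve, "sec_calibration"))
  10^(curve$intercept + curve$slope * volume)
}

#' Elution volume predicted for a molecular weight
#'
#' Inverse of [apparent_mw()] on the fitted line.
#'
#' @param curve a [fit_calibration()] result.
#' @param mw molecular weight, kDa.
#' @return Elution volume, ml.
#' @export
elution_volume_for_mw <- function(curve, mw) {
  stopifnot(inherits(curve, "sec_calibration"))
  (log10(mw) - curve$intercept) / curve$slope
}

#' Oligomeric-state call from an apparent/theoretical MW ratio
#'
#' Ratio bands (defaults): monomer below 1.4; dimer for ratios in
#' [1.4, 2.5] (both boundaries inclusive to the dimer band); oligomer
#' above 2.5.  When `expected_complex_mw` is supplied the call switches
#' to complex-consistency mode: `complex-consistent` when the apparent
#' MW is within 10% of the expected complex MW, otherwise the ratio
#' bands apply.  Ratios of at least 1.4 also carry the
#' extended/oligomeric annotation of [mw_anomaly()], since disordered
#' monomers elute anomalously early too.
#'
#' @param apparent apparent MW, kDa.
#' @param theoretical theoretical monomer MW, kDa.
#' @param thresholds numeric length-2: dimer lower bound and upper
#'   bound on the ratio scale (default `c(1.4, 2.5)`).
#' @param expected_complex_mw optional expected complex MW, kDa.
#' @param complex_tol relative tolerance for the complex call (0.10).
#' @return Object of class `oligomeric_state`: `apparent_mw`,
#'   `theoretical_mw`, `ratio`, `state_call`, `annotation`,
#'   `complex_deviation` (relative, when tested).
#' @export
call_oligomeric_state <- function(apparent, theoretical,
                                  thresholds = c(1.4, 2.5),
                                  expected_complex_mw = NULL,
                                  complex_tol = 0.10) {
  if (apparent <= 0 || theoretical <= 0)
    stop("molecular weights must be positive")
  ratio <- apparent / theoretical
  dev <- NA_real_
  if (!is.null(expected_complex_mw)) {
    dev <- abs(apparent - expected_complex_mw) / expected_complex_mw
    if (dev < complex_tol) {
      return(structure(list(apparent_mw = apparent,
                            theoretical_mw = theoretical, ratio = ratio,
                            state_call = "complex-consistent",
                            annotation = NA_character_,
                            complex_deviation = dev),
                       class = "oligomeric_state"))
    }
  }
  state <- if (ratio < thresholds[1]) "monomer"
           else if (ratio <= thresholds[2]) "dimer"
           else "oligomer"
  structure(list(apparent_mw = apparent, theoretical_mw = theoretical,
                 ratio = ratio, state_call = state,
                 annotation = mw_anomaly(apparent, theoretical)$annotation,
                 complex_deviation = dev),
            class = "oligomeric_state")
}

#' Oligomeric-state estimate from an elution volume
#'
#' Converts the volume to an apparent MW on the calibration line and
#' delegates to [call_oligomeric_state()].  Volumes outside the
#' calibrated range are flagged as extrapolated.
#'
#' @param volume elution volume, ml.
#' @param curve a [fit_calibration()] result.
#' @param theoretical_mw theoretical monomer MW, kDa.
#' @param ... passed to [call_oligomeric_state()].
#' @return An `oligomeric_state` with additional fields
#'   `elution_volume` and `extrapolated`.
#' @export
estimate_state <- function(volume, curve, theoretical_mw, ...) {
  app <- apparent_mw(curve, volume)
  out <- call_oligomeric_state(app, theoretical_mw, ...)
  out$elution_volume <- volume
  out$extrapolated <- volume < curve$volume_range[1] ||
    volume > curve$volume_range[2]
  if (out$extrapolated)
    warning("elution volume outside the calibrated range; result extrapolated")
  out
}

#' @export
print.oligomeric_state <- function(x, ...) {
  cat(sprintf("Apparent MW %.1f kDa / theoretical %.1f kDa (ratio %.2f) -> %s\n",
              x$apparent_mw, x$theoretical_mw, x$ratio, x$state_call))
  if (!is.na(x$complex_deviation))
    cat(sprintf("  deviation from expected complex MW: %.1f%%\n",
                100 * x$complex_deviation))
  invisible(x)
}
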