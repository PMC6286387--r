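## 1-D small-angle scattering profiles and closed-form synthetic scatterers.
##
## q is the modulus of the scattering vector, q = 4 pi sin(theta) / lambda,
## in inverse angstroms; intensities are in arbitrary units.

#' Construct a SAXS profile
#'
#' @param q scattering vector, 1/Angstrom, strictly increasing,
#'   within [0, 0.30] by convention of the supported beamline range.
#' @param I scattered intensity, arbitrary units.
#' @param sigma optional per-point uncertainty (same units as `I`).
#' @param concentration optional sample concentration, mg/ml (needed for
#'   molecular-weight estimation from I(0)).
#' @return Object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL, concentration = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I))
    stop("`q` and `I` must have equal length")
  if (any(diff(q) <= 0))
    stop("`q` must be strictly increasing")
  if (any(q < 0))
    stop("`q` must be non-negative")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("`sigma` must match `q` in length")
  }
  structure(list(q = q, I = I, sigma = sigma, concentration = concentration),
            class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile: %d points, q in [%.4g, %.4g] 1/A%s\n",
              length(x$q), min(x$q), max(x$q),
              if (!is.null(x$concentration))
                sprintf(", %.2g mg/ml", x$concentration) else ""))
  invisible(x)
}

#' Default q grid for synthetic profiles
#'
#' Linear grid from the beamstop guard to 0.30 1/A in steps of 0.001,
#' emulating a reduced, merged beamline curve.
#'
#' @param q_min,q_max,dq grid limits and spacing, 1/Angstrom.
#' @return Numeric vector of q values.
#' @export
default_q_grid <- function(q_min = 0.008, q_max = 0.30, dq = 0.001) {
  seq(q_min, q_max, by = dq)
}

add_counting_noise <- function(I, noise) {
  ## Counting-statistics-like noise: sd proportional to sqrt(I), scaled so
  ## `noise` is the relative sd at the profile maximum.
  sigma <- noise * max(I) * sqrt(I / max(I))
  list(I = I + stats::rnorm(length(I), sd = sigma), sigma = sigma)
}

#' Synthetic uniform-sphere scattering profile
#'
#' Form factor of a homogeneous sphere of radius \eqn{R = R_g\sqrt{5/3}}:
#' \deqn{I(q) = I_0\left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2.}
#'
#' @param Rg radius of gyration, Angstrom.
#' @param I0 forward scattering intensity.
#' @param q_grid q values, 1/Angstrom; defaults to [default_q_grid()].
#' @param noise relative Gaussian noise level at the profile maximum
#'   (sd proportional to sqrt(I), emulating counting statistics); 0 for
#'   a noiseless curve.  Uses the current RNG state; seed upstream.
#' @param concentration optional mg/ml tag carried on the profile.
#' @return A [saxs_profile()].
#' @examples
#' p <- synth_sphere(Rg = 31.3, I0 = 1)
#' p$I[1] < 1                       # I(q>0) below the forward limit
#' @export
synth_sphere <- function(Rg, I0 = 1, q_grid = default_q_grid(), noise = 0,
                         concentration = NULL) {
  if (Rg <= 0) stop("`Rg` must be positive")
  if (I0 <= 0) stop("`I0` must be positive")
  R <- Rg * sqrt(5 / 3)
  x <- q_grid * R
  ## series below x = 0.1: sin(x) - x cos(x) loses all precision there
  amp <- ifelse(x < 0.1,
                1 - x^2 / 10 + x^4 / 280,
                3 * (sin(x) - x * cos(x)) / x^3)
  I <- I0 * amp^2
  sigma <- NULL
  if (noise > 0) {
    nz <- add_counting_noise(I, noise)
    I <- nz$I; sigma <- nz$sigma
  }
  saxs_profile(q_grid, I, sigma, concentration)
}

#' Synthetic Debye (Gaussian chain) scattering profile
#'
#' Scattering of an ideal unfolded chain, with \eqn{x = q^2 R_g^2}:
#' \deqn{I(q) = I_0\, 2(e^{-x} - 1 + x)/x^2.}
#'
#' @inheritParams synth_sphere
#' @return A [saxs_profile()].
#' @examples
#' p <- synth_debye_chain(Rg = 30.4, I0 = 1)
#' @export
synth_debye_chain <- function(Rg, I0 = 1, q_grid = default_q_grid(),
                              noise = 0, concentration = NULL) {
  if (Rg <= 0) stop("`Rg` must be positive")
  if (I0 <= 0) stop("`I0` must be positive")
  x <- (q_grid * Rg)^2
  ## expm1 keeps the small-x limit (I -> I0) exact
  I <- ifelse(x == 0, I0, I0 * 2 * (expm1(-x) + x) / x^2)
  sigma <- NULL
  if (noise > 0) {
    nz <- add_counting_noise(I, noise)
    I <- nz$I; sigma <- nz$sigma
  }
  saxs_profile(q_grid, I, sigma, concentration)
}
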