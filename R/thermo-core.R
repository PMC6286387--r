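## Thermodynamic identities shared by every fitting module.
##
## All energies are in kcal/mol, temperatures in kelvin, association
## constants in M^-1.  Values are stored at full precision; rounding is a
## display concern only (see display_round()).

#' Gas constant in kcal mol^-1 K^-1
#'
#' @format Numeric scalar, 1.9872e-3 kcal mol^-1 K^-1.
#' @export
R_KCAL <- 1.9872e-3

#' Convert Celsius to kelvin
#'
#' @param temp_c temperature in degrees Celsius.
#' @return Temperature in kelvin (`temp_c + 273.15`).
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + 273.15
}

#' Binding free energy from an association constant
#'
#' Computes \eqn{\Delta G = -R T \ln K_b} for a bimolecular association
#' with standard-state concentration 1 M.
#'
#' @param Kb association constant, M^-1; must be positive.
#' @param T_k absolute temperature, kelvin; must be positive.
#' @return Free-energy change in kcal/mol (negative for Kb > 1).
#' @examples
#' delta_g_from_kb(1.2e7, 303.15)   # approx -9.82 kcal/mol
#' @export
delta_g_from_kb <- function(Kb, T_k) {
  if (!is.numeric(Kb) || any(!is.finite(Kb)) || any(Kb <= 0))
    stop("`Kb` must be a positive finite association constant (M^-1)")
  if (!is.numeric(T_k) || any(!is.finite(T_k)) || any(T_k <= 0))
    stop("`T_k` must be a positive absolute temperature (K)")
  -R_KCAL * T_k * log(Kb)
}

#' Association constant from a binding free energy
#'
#' Inverse of [delta_g_from_kb()].
#'
#' @param dG free-energy change, kcal/mol.
#' @param T_k absolute temperature, kelvin.
#' @return Association constant in M^-1.
#' @export
kb_from_delta_g <- function(dG, T_k) {
  if (!is.numeric(T_k) || any(T_k <= 0))
    stop("`T_k` must be a positive absolute temperature (K)")
  exp(-dG / (R_KCAL * T_k))
}

#' Entropic term -TdS from the enthalpy/free-energy split
#'
#' @param dG free-energy change, kcal/mol.
#' @param dH enthalpy change, kcal/mol.
#' @return `-T dS = dG - dH`, kcal/mol.
#' @export
entropy_term <- function(dG, dH) {
  stopifnot(is.numeric(dG), is.numeric(dH))
  dG - dH
}

#' Ratio of two association constants, as a percentage
#'
#' @param Kb_a,Kb_b association constants, M^-1; both positive.
#' @return `100 * Kb_a / Kb_b`.
#' @export
kb_ratio_percent <- function(Kb_a, Kb_b) {
  if (!is.numeric(Kb_a) || any(Kb_a <= 0))
    stop("`Kb_a` must be positive")
  if (!is.numeric(Kb_b) || any(Kb_b <= 0))
    stop("`Kb_b` must be positive")
  100 * Kb_a / Kb_b
}

#' Round half away from zero for table display
#'
#' `round()` in R rounds half to even; published thermodynamic tables
#' round half away from zero.  Internal values are never rounded; this
#' helper exists purely for formatting.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
display_round <- function(x, digits = 2) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

#' Full thermodynamic description of a binding equilibrium
#'
#' Bundles the three fitted ITC parameters with the derived free-energy
#' decomposition at the experiment temperature.  The identities
#' `dG = -RT ln Kb` and `mTdS = dG - dH` hold by construction.
#'
#' @param Kb association constant, M^-1.
#' @param n stoichiometry (sites per molecule of cell species).
#' @param dH enthalpy change, kcal/mol of injectant.
#' @param T_k absolute temperature, kelvin.
#' @return An object of class `binding_thermo`: a list with fields
#'   `Kb`, `n`, `dH`, `T_k`, `dG`, `mTdS`.
#' @examples
#' bt <- binding_thermo(Kb = 2.9e7, n = 1.06, dH = -6.9,
#'                      T_k = celsius_to_kelvin(30))
#' bt$dG    # approx -10.35 kcal/mol
#' bt$mTdS  # approx -3.45 kcal/mol
#' @export
binding_thermo <- function(Kb, n, dH, T_k) {
  if (!is.numeric(n) || n <= 0)
    stop("`n` (stoichiometry) must be positive")
  dG <- delta_g_from_kb(Kb, T_k)
  out <- list(Kb = Kb, n = n, dH = dH, T_k = T_k,
              dG = dG, mTdS = entropy_term(dG, dH))
  class(out) <- "binding_thermo"
  out
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat("Binding thermodynamics at", format(x$T_k), "K\n")
  cat(sprintf("  Kb    = %.3g M^-1\n", x$Kb))
  cat(sprintf("  n     = %.3f\n", x$n))
  cat(sprintf("  dH    = %.2f kcal/mol\n", x$dH))
  cat(sprintf("  dG    = %.2f kcal/mol\n", x$dG))
  cat(sprintf("  -TdS  = %.2f kcal/mol\n", x$mTdS))
  invisible(x)
}
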