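#' Na/K-ATPase pump activation
#'
#' Saturable activation of the pump by its two substrates,
#' `B = [C_K_IS / (C_K_IS + Ch_K)] [C_Na_IC / (C_Na_IC + Ch_Na)]`,
#' a product of two Michaelis factors in interstitial potassium and
#' intracellular sodium. `B` lies in `[0, 1)` and increases in both
#' arguments.
#'
#' @param c_K_IS interstitial potassium concentration (mmol/L).
#' @param c_Na_IC intracellular sodium concentration (mmol/L).
#' @param fixed an [hd_fixed_params()] list (`Ch_K`, `Ch_Na`).
#' @return dimensionless activation in `[0, 1)`.
#' @export
pump_activation <- function(c_K_IS, c_Na_IC, fixed = hd_fixed_params()) {
  if (any(c_K_IS < 0) || any(c_Na_IC < 0))
    stop("concentrations must be non-negative")
  (c_K_IS / (c_K_IS + fixed$Ch_K)) * (c_Na_IC / (c_Na_IC + fixed$Ch_Na))
}

# Signed pump stoichiometry: 3 Na out of, 2 K into, the cell per cycle.
H_NA <- -3
H_K  <- 2

#' Calibrate transmembrane ion diffusivities to the pre-dialysis steady
#' state
#'
#' At t = 0 the passive and active components of sodium and potassium
#' transport must cancel, which ties each diffusivity to the pump:
#' `w_s = -H_s B0 Jp_max / (C_s_IS0 - C_s_IC0)` with `H_Na = -3`,
#' `H_K = +2` and `B0` the initial pump activation. With physiological
#' gradients (extracellular sodium high, intracellular potassium high)
#' both diffusivities come out positive.
#'
#' @param Jp_max maximum pump transfer rate (mmol/min).
#' @param c_Na_IS0,c_Na_IC0 initial interstitial and intracellular sodium
#'   (mmol/L).
#' @param c_K_IS0,c_K_IC0 initial interstitial and intracellular
#'   potassium (mmol/L).
#' @param fixed an [hd_fixed_params()] list.
#' @return named vector `c(w_Na, w_K)` in mL/min.
#' @export
calibrate_diffusivities <- function(Jp_max, c_Na_IS0, c_Na_IC0,
                                    c_K_IS0, c_K_IC0,
                                    fixed = hd_fixed_params()) {
  stopifnot(Jp_max >= 0)
  if (c_Na_IS0 == c_Na_IC0 || c_K_IS0 == c_K_IC0)
    stop("equal initial concentrations leave the diffusivity undetermined")
  B0 <- pump_activation(c_K_IS0, c_Na_IC0, fixed)
  w_Na <- -H_NA * B0 * Jp_max / (c_Na_IS0 - c_Na_IC0) * 1000
  w_K  <- -H_K  * B0 * Jp_max / (c_K_IS0 - c_K_IC0) * 1000
  if (w_Na < 0 || w_K < 0)
    stop("calibration produced a negative diffusivity; check gradients")
  c(w_Na = w_Na, w_K = w_K)
}

#' Sodium or potassium flux across the cell membrane
#'
#' Passive diffusion plus the pump contribution,
#' `J_s = w_s (C_s_IS - C_s_IC) + H_s B Jp_max`, positive into the cell.
#' The pump moves 3 Na out (`H_Na = -3`) and 2 K in (`H_K = +2`) per
#' cycle.
#'
#' @param solute `"na"` or `"k"`.
#' @param c_IS,c_IC interstitial and intracellular concentrations
#'   (mmol/L).
#' @param w_s transmembrane diffusivity for this ion (mL/min).
#' @param B pump activation from [pump_activation()].
#' @param Jp_max maximum pump rate (mmol/min).
#' @return flux (mmol/min), positive into the cell.
#' @export
ion_flux <- function(solute = c("na", "k"), c_IS, c_IC, w_s, B, Jp_max) {
  solute <- match.arg(solute)
  H <- if (solute == "na") H_NA else H_K
  w_s / 1000 * (c_IS - c_IC) + H * B * Jp_max
}

#' Urea flux across the cell membrane
#'
#' Pure passive diffusion `J = k_U (C_IS - C_IC)`, positive into the
#' cell.
#'
#' @param c_IS,c_IC concentrations (mmol/L).
#' @param k_U urea diffusivity (mL/min), non-negative.
#' @return flux (mmol/min).
#' @export
urea_flux <- function(c_IS, c_IC, k_U = hd_fixed_params()$k_U) {
  stopifnot(k_U >= 0)
  k_U / 1000 * (c_IS - c_IC)
}

#' Generic solute A flux (Expanded model)
#'
#' Diffusion with a built-in equilibrium ratio,
#' `J = w_A (C_A_IS - gamma C_A_IC)`, positive into the cell. `gamma` is
#' the initial interstitial-to-intracellular concentration ratio, so the
#' flux vanishes at the initial state by construction.
#'
#' @param c_A_IS,c_A_IC concentrations (mmol/L).
#' @param w_A diffusivity (mL/min).
#' @param gamma equilibrium concentration ratio.
#' @return flux (mmol/min).
#' @export
soluteA_flux <- function(c_A_IS, c_A_IC, w_A, gamma) {
  stopifnot(w_A >= 0, gamma > 0)
  w_A / 1000 * (c_A_IS - gamma * c_A_IC)
}

#' Total osmolarity of a compartment
#'
#' `Theta = phi (C_Na + C_K + C_U [+ C_A] + C_TP + M_eq / V)` where
#' `phi` is the osmotic activity coefficient, `C_TP` is protein in
#' mmol/L, and `M_eq` is the constant equivalent mass of every osmole the
#' model does not describe explicitly.
#'
#' @param c_Na,c_K,c_U small-solute concentrations (mmol/L).
#' @param c_TP_mmol protein concentration (mmol/L); 0 for the
#'   intracellular compartment, whose protein osmoles sit inside `M_eq`.
#' @param M_eq equivalent mass (mmol).
#' @param V compartment volume (L), positive.
#' @param osm_coeff osmotic activity coefficient.
#' @param c_A Expanded-model solute A concentration (mmol/L), or 0.
#' @return osmolarity (mmol/L).
#' @export
osmolarity <- function(c_Na, c_K, c_U, c_TP_mmol, M_eq, V,
                       osm_coeff = hd_fixed_params()$osm_coeff, c_A = 0) {
  if (any(V <= 0)) stop("compartment volume must be positive")
  if (any(c(c_Na, c_K, c_U, c_TP_mmol, M_eq, c_A) < 0))
    stop("concentrations and masses must be non-negative")
  osm_coeff * (c_Na + c_K + c_U + c_A + c_TP_mmol + M_eq / V)
}

#' Osmotic water flux across the cell membrane
#'
#' `Jv_ISIC = k_f (Theta_IC - Theta_IS)`, positive into the cell: cells
#' take up water when their interior is hypertonic relative to the
#' interstitium.
#'
#' @param theta_IC,theta_IS intracellular and interstitial osmolarities
#'   (mmol/L).
#' @param k_f water transfer coefficient (L^2 min^-1 mmol^-1).
#' @return flux (L/min), positive into the cell.
#' @export
water_flux <- function(theta_IC, theta_IS, k_f = hd_fixed_params()$k_f) {
  stopifnot(k_f >= 0)
  k_f * (theta_IC - theta_IS)
}
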