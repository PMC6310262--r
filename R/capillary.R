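#' Oncotic pressure of plasma proteins (Landis-Pappenheimer)
#'
#' Colloid osmotic pressure as a cubic polynomial in total protein
#' concentration: `Pi = 2.1 c + 0.16 c^2 + 0.009 c^3` with `c` in g/dL.
#'
#' @param c_tp total protein concentration (g/dL), non-negative.
#' @return oncotic pressure (mmHg).
#' @export
oncotic_pressure <- function(c_tp) {
  if (any(c_tp < 0)) stop("protein concentration must be non-negative")
  2.1 * c_tp + 0.16 * c_tp^2 + 0.009 * c_tp^3
}

#' Steric reflection coefficient from solute and pore radii
#'
#' Two-pore-theory steric form `sigma = [1 - (1 - lambda)^2]^2` with
#' `lambda = solute_radius / pore_radius`, clipped to 1 for solutes at
#' least as large as the pore.
#'
#' @param solute_radius,pore_radius radii (Angstrom), positive.
#' @param sigma_fn optional override: a function of `lambda` returning a
#'   reflection coefficient in `[0, 1]`.
#' @return dimensionless reflection coefficient in `[0, 1]`.
#' @export
reflection_coefficient <- function(solute_radius, pore_radius,
                                   sigma_fn = NULL) {
  if (any(solute_radius <= 0) || any(pore_radius <= 0))
    stop("radii must be positive")
  lambda <- solute_radius / pore_radius
  if (!is.null(sigma_fn)) return(pmin(1, pmax(0, sigma_fn(lambda))))
  ifelse(lambda >= 1, 1, (1 - (1 - lambda)^2)^2)
}

# Bungay-Brenner (1973) centerline drag expansion for diffusion in a
# cylindrical pore: H = 6*pi/Kt. Valid over the full lambda range, which
# matters here because protein in the small pores sits at lambda ~ 0.79.
bungay_Kt <- function(lambda) {
  a <- c(-73 / 60, 77.293 / 50.400, -22.5083, -5.6117, -0.3363, -1.216, 1.647)
  om <- 1 - lambda
  (9 / 4) * pi^2 * sqrt(2) * om^(-5 / 2) * (1 + a[1] * om + a[2] * om^2) +
    a[3] + a[4] * lambda + a[5] * lambda^2 + a[6] * lambda^3 + a[7] * lambda^4
}

hindrance_factor <- function(lambda, method = c("bungay", "centerline")) {
  method <- match.arg(method)
  if (method == "bungay") {
    6 * pi / bungay_Kt(lambda)
  } else {
    1 - 2.1044 * lambda + 2.089 * lambda^3 - 0.948 * lambda^5
  }
}

# Stokes-Einstein free diffusivity in plasma, cm^2/min.
free_diffusivity <- function(radius_A, viscosity_mPas, temperature_K) {
  kB <- 1.380649e-23                      # J/K
  r_m <- radius_A * 1e-10
  D_m2s <- kB * temperature_K / (6 * pi * viscosity_mPas * 1e-3 * r_m)
  D_m2s * 1e4 * 60
}

#' Per-pore hydraulics and protein permeability
#'
#' Splits the global capillary filtration coefficient over the three pore
#' populations and derives, for each, the protein reflection coefficient
#' and the diffusive permeability-surface product. The effective pore
#' area over diffusion length comes from Poiseuille flow,
#' `(A0/dx)_r = 8 eta Lp_r / r^2`, and
#' `PS_r = (A0/dx)_r D_free Phi(lambda) H(lambda)` with steric partition
#' `Phi = (1 - lambda)^2` and diffusive hindrance `H`. Ultrasmall pores
#' are water-only: `sigma = 1`, `PS = 0`.
#'
#' @param Lp global capillary filtration coefficient (mL/min/mmHg).
#' @param alpha_LP large-pore fraction of `Lp`.
#' @param fixed an [hd_fixed_params()] list (pore radii, protein radius,
#'   viscosity, temperature, small-pore fraction, hindrance rule).
#' @return a data.frame with one row per pore population (`LP`, `SP`,
#'   `UP`): `radius` (Angstrom), `alpha`, `Lp_r` (mL/min/mmHg), `sigma`,
#'   `PS` (mL/min).
#' @export
pore_hydraulics <- function(Lp, alpha_LP, fixed = hd_fixed_params()) {
  Lp <- unname(Lp); alpha_LP <- unname(alpha_LP)
  stopifnot(Lp > 0, alpha_LP >= 0)
  alpha_UP <- 1 - fixed$alpha_SP - alpha_LP
  if (alpha_UP < 0) stop("alpha_LP + alpha_SP exceeds 1")
  radius <- c(LP = fixed$r_LP, SP = fixed$r_SP, UP = fixed$r_UP)
  alpha <- c(LP = alpha_LP, SP = fixed$alpha_SP, UP = alpha_UP)
  sigma <- vapply(radius, function(r)
    reflection_coefficient(fixed$r_protein, r, fixed$sigma_fn), numeric(1))
  sigma[["UP"]] <- 1
  Lp_r <- alpha * Lp
  D <- free_diffusivity(fixed$r_protein, fixed$viscosity, fixed$temperature)
  # viscosity mPa.s -> mmHg.min; radius A -> cm; (A0/dx) in cm; PS in mL/min
  eta <- fixed$viscosity * 1e-3 / 133.322 / 60
  PS <- numeric(3)
  names(PS) <- names(radius)
  for (p in c("LP", "SP")) {
    lambda <- fixed$r_protein / radius[[p]]
    if (lambda >= 1) { PS[[p]] <- 0; next }
    r_cm <- radius[[p]] * 1e-8
    A0dx <- 8 * eta * Lp_r[[p]] / r_cm^2
    Phi <- (1 - lambda)^2
    PS[[p]] <- A0dx * D * Phi * hindrance_factor(lambda, fixed$hindrance)
  }
  PS[["UP"]] <- 0
  data.frame(pore = names(radius), radius = unname(radius),
             alpha = unname(alpha), Lp_r = unname(Lp_r),
             sigma = unname(sigma), PS = unname(PS))
}

#' Interstitial hydraulic pressure from interstitial volume
#'
#' Linear pressure-volume relation
#' `P_IS = P_IS0 + (V_IS - V_IS0) / compliance`.
#'
#' @param V_IS interstitial volume (L), positive.
#' @param V_IS0 baseline interstitial volume (L).
#' @param fixed an [hd_fixed_params()] list (`P_IS0`, `compliance`).
#' @return pressure (mmHg).
#' @export
interstitial_pressure <- function(V_IS, V_IS0, fixed = hd_fixed_params()) {
  if (any(V_IS <= 0)) stop("interstitial volume must be positive")
  fixed$P_IS0 + (V_IS - V_IS0) / fixed$compliance
}

#' Transcapillary fluid flux through the three pore populations
#'
#' Starling-type filtration for each pore population
#' `Jv_r = alpha_r Lp [(P_c - P_IS) - sigma_r (Pi_P - Pi_IS)]`; the
#' total flux is their sum,
#' `Jv_ISP = Lp [(P_c - P_IS) - sum_r alpha_r sigma_r (Pi_P - Pi_IS)]`.
#' Positive values are plasma-to-interstitium filtration.
#'
#' @param P_c capillary hydraulic pressure (mmHg).
#' @param P_IS interstitial hydraulic pressure (mmHg).
#' @param Pi_P,Pi_IS plasma and interstitial oncotic pressures (mmHg).
#' @param pores per-pore table from [pore_hydraulics()].
#' @return list with `total` (mL/min) and named per-pore vector `per_pore`.
#' @export
capillary_fluid_flux <- function(P_c, P_IS, Pi_P, Pi_IS, pores) {
  dP <- P_c - P_IS
  dPi <- Pi_P - Pi_IS
  Jv_r <- pores$Lp_r * (dP - pores$sigma * dPi)
  names(Jv_r) <- pores$pore
  list(total = sum(Jv_r), per_pore = Jv_r)
}

#' Mean intramembrane solute concentration
#'
#' Flow-weighted mean concentration inside a pore,
#' `C_m = f c_up + (1 - f) c_down` with
#' `f(Pe) = 1/(1 - e^{-Pe}) - 1/Pe` (Patlak weighting). `Pe` is the
#' in-pore Peclet number, signed with the flow from the `c_up` side to
#' the `c_down` side; `f -> 1/2` as `Pe -> 0` (diffusion-dominated),
#' `f -> 1` as `Pe -> +Inf` (pure convection from the upstream side) and
#' `f -> 0` as `Pe -> -Inf`.
#'
#' @param c_up,c_down concentrations at the two pore mouths.
#' @param Pe signed Peclet number.
#' @return concentration, always within `[min(c_up, c_down), max(...)]`.
#' @export
mean_membrane_concentration <- function(c_up, c_down, Pe) {
  if (any(c_up < 0) || any(c_down < 0))
    stop("concentrations must be non-negative")
  f <- peclet_weight(Pe)
  f * c_up + (1 - f) * c_down
}

peclet_weight <- function(Pe) {
  ifelse(abs(Pe) < 1e-6,
         0.5 + Pe / 12,                      # series limit about Pe = 0
         ifelse(Pe > 500, 1,
                ifelse(Pe < -500, 0,
                       1 / (1 - exp(-Pe)) - 1 / Pe)))
}

#' Transcapillary protein flux through large and small pores
#'
#' Kedem-Katchalsky diffusion plus sieved convection for each permeable
#' pore population:
#' `J_TP_r = PS_r (C_P - C_IS) + (1 - sigma_r) Jv_r C_m_r`, where the
#' intramembrane mean `C_m_r` uses the Peclet number
#' `Pe_r = (1 - sigma_r) Jv_r / PS_r`. Ultrasmall pores carry no protein.
#'
#' @param C_P,C_IS plasma and interstitial protein concentrations (any
#'   consistent unit; flux returned in that unit times mL/min).
#' @param Jv_per_pore named per-pore fluid fluxes (mL/min) from
#'   [capillary_fluid_flux()].
#' @param pores per-pore table from [pore_hydraulics()].
#' @return total protein flux, positive plasma-to-interstitium.
#' @export
protein_flux <- function(C_P, C_IS, Jv_per_pore, pores) {
  J <- 0
  for (p in c("LP", "SP")) {
    i <- match(p, pores$pore)
    S <- 1 - pores$sigma[i]
    Jv <- Jv_per_pore[[p]]
    PS <- pores$PS[i]
    if (PS > 0) {
      Pe <- S * Jv / PS
      Cm <- mean_membrane_concentration(C_P, C_IS, Pe)
      J <- J + PS * (C_P - C_IS) + S * Jv * Cm
    } else {
      Cm <- if (Jv >= 0) C_P else C_IS   # pure-convection limit
      J <- J + S * Jv * Cm
    }
  }
  J
}

#' Lymphatic fluid and protein return
#'
#' Lymph flow rises linearly with interstitial pressure,
#' `Jv_L = Jv_lymph0 [1 + LS (P_IS - P_IS0)]`, clamped at zero from
#' below (lymphatics do not reverse); lymph carries interstitial fluid
#' unsieved, so `J_TP_L = C_TP_IS Jv_L`. Positive values are
#' interstitium-to-plasma.
#'
#' @param P_IS interstitial pressure (mmHg).
#' @param C_TP_IS interstitial protein concentration.
#' @param Jv_lymph0 baseline lymph flow (mL/min).
#' @param fixed an [hd_fixed_params()] list (`LS`, `P_IS0`).
#' @return list with `Jv_L` (mL/min) and `J_TP_L`.
#' @export
lymph_flow <- function(P_IS, C_TP_IS, Jv_lymph0, fixed = hd_fixed_params()) {
  Jv_L <- pmax(0, Jv_lymph0 * (1 + fixed$LS * (P_IS - fixed$P_IS0)))
  list(Jv_L = Jv_L, J_TP_L = C_TP_IS * Jv_L)
}
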