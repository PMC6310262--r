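#' Fixed model constants
#'
#' Returns the set of model constants that are held fixed during a session
#' and shared across patients. Defaults are the values used throughout the
#' package: the three-pore geometry of the capillary wall, the
#' Na/K-ATPase half-activation constants, the urea and water transfer
#' coefficients, the interstitial pressure-volume relation and the
#' intracellular/plasma equilibrium ratios.
#'
#' Units are fixed: volumes L, flows mL/min, pressures mmHg, small-solute
#' concentrations mmol/L, total protein g/dL (molecular weight 69 g/mmol
#' for osmotic bookkeeping), pore and solute radii Angstrom.
#'
#' @param alpha_SP small-pore fraction of the capillary hydraulic
#'   conductance (dimensionless). The large-pore fraction is a per-session
#'   estimated quantity; the ultrasmall fraction is `1 - alpha_SP - alpha_LP`.
#' @param R0 pre-dialysis interstitial-to-plasma total protein
#'   concentration ratio.
#' @param LS lymph-flow sensitivity to interstitial pressure (1/mmHg).
#' @param k_U urea diffusivity across the cell membrane (mL/min).
#' @param k_f transmembrane water transfer coefficient
#'   (L^2 min^-1 mmol^-1).
#' @param r_LP,r_SP,r_UP pore radii (Angstrom).
#' @param r_protein protein (albumin-size) molecular radius (Angstrom).
#' @param ratio_Na,ratio_K,ratio_U intracellular-to-plasma equilibrium
#'   concentration ratios used for the initial state.
#' @param Ch_Na,Ch_K pump half-activation concentrations (mmol/L) for
#'   intracellular sodium and interstitial potassium.
#' @param osm_coeff osmotic activity coefficient applied to total
#'   osmolarity.
#' @param offset_Na,offset_K,offset_U,offset_A constant
#'   interstitial/plasma concentration ratios for the small solutes
#'   (interstitial concentration is `offset * plasma`).
#' @param P_IS0 baseline interstitial hydraulic pressure (mmHg).
#' @param compliance interstitial pressure-volume slope (L/mmHg); the
#'   interstitial pressure is linear in interstitial volume with this
#'   slope.
#' @param viscosity plasma viscosity (mPa s), used for the Poiseuille
#'   area-over-length of each pore population.
#' @param temperature absolute temperature (K) for the Stokes-Einstein
#'   free diffusivity of protein.
#' @param MW_protein protein molecular weight (g/mmol).
#' @param cA_EC0,cA_IC0 Expanded-model extracellular (plasma) and
#'   intracellular concentrations of the additional generic solute A
#'   (mmol/L).
#' @param sigma_fn steric reflection-coefficient rule: a function of
#'   `lambda = solute_radius / pore_radius` returning a value in `[0, 1]`.
#' @param hindrance one of `"bungay"` (Bungay-Brenner diffusive drag,
#'   valid over the whole radius-ratio range; default) or `"centerline"`
#'   (classical centerline polynomial, accurate only for small ratios).
#' @return a list of class `hd_fixed` with the above fields.
#' @export
hd_fixed_params <- function(alpha_SP = 0.6,
                            R0 = 0.6,
                            LS = 0.4,
                            k_U = 770,
                            k_f = 0.024,
                            r_LP = 250, r_SP = 45, r_UP = 2,
                            r_protein = 35.5,
                            ratio_Na = 0.0714, ratio_K = 35, ratio_U = 1,
                            Ch_Na = 10, Ch_K = 1.5,
                            osm_coeff = 0.93,
                            offset_Na = 0.98, offset_K = 0.98,
                            offset_U = 1.0, offset_A = 0.98,
                            P_IS0 = 2.0,
                            compliance = 1.0,
                            viscosity = 1.2,
                            temperature = 310,
                            MW_protein = 69,
                            cA_EC0 = 110, cA_IC0 = 4.4,
                            sigma_fn = NULL,
                            hindrance = c("bungay", "centerline")) {
  hindrance <- match.arg(hindrance)
  stopifnot(alpha_SP > 0, alpha_SP < 1, R0 > 0, R0 <= 1, LS >= 0,
            k_U >= 0, k_f >= 0, r_LP > 0, r_SP > 0, r_UP > 0,
            r_protein > 0, Ch_Na > 0, Ch_K > 0,
            osm_coeff > 0, osm_coeff <= 1, compliance > 0,
            viscosity > 0, temperature > 0, MW_protein > 0)
  out <- list(alpha_SP = alpha_SP, R0 = R0, LS = LS, k_U = k_U, k_f = k_f,
              r_LP = r_LP, r_SP = r_SP, r_UP = r_UP, r_protein = r_protein,
              ratio_Na = ratio_Na, ratio_K = ratio_K, ratio_U = ratio_U,
              Ch_Na = Ch_Na, Ch_K = Ch_K, osm_coeff = osm_coeff,
              offset_Na = offset_Na, offset_K = offset_K,
              offset_U = offset_U, offset_A = offset_A,
              P_IS0 = P_IS0, compliance = compliance,
              viscosity = viscosity, temperature = temperature,
              MW_protein = MW_protein, cA_EC0 = cA_EC0, cA_IC0 = cA_IC0,
              sigma_fn = sigma_fn, hindrance = hindrance)
  class(out) <- "hd_fixed"
  out
}

#' Per-session patient descriptor
#'
#' Bundles everything measured before and during one dialysis session:
#' pre-dialysis compartment volumes, plasma concentrations, and the
#' treatment settings (session length, blood and ultrafiltration flows,
#' dialysances and dialysate concentrations).
#'
#' @param id session identifier string.
#' @param V_P0 pre-dialysis plasma volume (L).
#' @param ECV0 pre-dialysis extracellular volume (L); interstitial volume
#'   is `ECV0 - V_P0`.
#' @param ICV0 pre-dialysis intracellular volume (L).
#' @param tp_gdl plasma total protein (g/dL).
#' @param na,k,urea,glucose pre-dialysis plasma concentrations (mmol/L).
#' @param MAP mean arterial pressure (mmHg); carried as metadata only.
#' @param duration session length (min).
#' @param Qb blood flow in the dialysis circuit (mL/min).
#' @param Juf ultrafiltration rate (mL/min).
#' @param D_na,D_k,D_urea dialysances (mL/min). `D_na` defaults to the
#'   urea value when `NA` (sodium dialysance is rarely reported and is
#'   taken equal to urea clearance).
#' @param Cd_na,Cd_k,Cd_urea dialysate concentrations (mmol/L).
#' @param ramp ultrafiltration onset profile, `"none"` (constant from
#'   t = 0) or `"exponential"` (UF and dialysances rise as
#'   `lambda (e^{0.1 t} - 1)` and reach the treatment value at 10 min).
#' @param variant `"baseline"` or `"expanded"` (adds the generic solute A).
#' @return a list of class `hd_patient`.
#' @export
hd_patient <- function(id = "patient",
                       V_P0, ECV0, ICV0,
                       tp_gdl, na, k, urea, glucose,
                       MAP = NA_real_,
                       duration, Qb, Juf,
                       D_na = NA_real_, D_k, D_urea,
                       Cd_na, Cd_k, Cd_urea = 0,
                       ramp = c("none", "exponential"),
                       variant = c("baseline", "expanded")) {
  ramp <- match.arg(ramp)
  variant <- match.arg(variant)
  if (is.na(D_na)) D_na <- D_urea
  stopifnot(V_P0 > 0, ECV0 > V_P0, ICV0 > 0,
            tp_gdl > 0, na > 0, k > 0, urea > 0, glucose > 0,
            duration > 0, Qb > 0, Juf >= 0, Juf < Qb,
            D_na >= 0, D_k >= 0, D_urea >= 0,
            Cd_na >= 0, Cd_k >= 0, Cd_urea >= 0)
  out <- list(id = id, V_P0 = V_P0, ECV0 = ECV0, ICV0 = ICV0,
              tp_gdl = tp_gdl, na = na, k = k, urea = urea,
              glucose = glucose, MAP = MAP,
              duration = duration, Qb = Qb, Juf = Juf,
              D_na = D_na, D_k = D_k, D_urea = D_urea,
              Cd_na = Cd_na, Cd_k = Cd_k, Cd_urea = Cd_urea,
              ramp = ramp, variant = variant)
  class(out) <- "hd_patient"
  out
}

#' Median virtual patient
#'
#' The cohort-median session: every quantity set to the published median
#' of the corresponding study column (first or last weekly session).
#'
#' @param session `"hd1"` (first session of the week, 3-day interdialytic
#'   interval) or `"hd3"` (last session).
#' @param variant model variant passed through to [hd_patient()].
#' @param ramp ultrafiltration onset profile.
#' @return an `hd_patient`.
#' @export
hd_median_patient <- function(session = c("hd1", "hd3"),
                              variant = c("baseline", "expanded"),
                              ramp = c("none", "exponential")) {
  session <- match.arg(session)
  variant <- match.arg(variant)
  ramp <- match.arg(ramp)
  if (session == "hd1") {
    hd_patient(id = "median-hd1",
               V_P0 = 3.2, ECV0 = 16.3, ICV0 = 14.5,
               tp_gdl = 6.5, na = 140.0, k = 5.6, urea = 55.2,
               glucose = 4.7, MAP = 93.0,
               duration = 238, Qb = 265, Juf = 11.5,
               D_k = 153.7, D_urea = 220.9,
               Cd_na = 142.0, Cd_k = 3.0, Cd_urea = 0,
               ramp = ramp, variant = variant)
  } else {
    hd_patient(id = "median-hd3",
               V_P0 = 3.0, ECV0 = 15.5, ICV0 = 15.0,
               tp_gdl = 6.6, na = 140.0, k = 5.4, urea = 46.2,
               glucose = 4.7, MAP = 90.3,
               duration = 240, Qb = 280, Juf = 9.2,
               D_k = 146.9, D_urea = 201.3,
               Cd_na = 142.0, Cd_k = 2.9, Cd_urea = 0,
               ramp = ramp, variant = variant)
  }
}

#' @export
print.hd_patient <- function(x, ...) {
  cat(sprintf("<hd_patient %s (%s)>\n", x$id, x$variant))
  cat(sprintf("  volumes (L): V_P %.2f  ECV %.2f  ICV %.2f\n",
              x$V_P0, x$ECV0, x$ICV0))
  cat(sprintf("  plasma: TP %.2f g/dL  Na %.1f  K %.2f  urea %.1f  glucose %.1f mmol/L\n",
              x$tp_gdl, x$na, x$k, x$urea, x$glucose))
  cat(sprintf("  session: %d min, Qb %.0f, UF %.1f mL/min, ramp %s\n",
              round(x$duration), x$Qb, x$Juf, x$ramp))
  invisible(x)
}

#' Default bounds for the estimated parameter triple
#'
#' Search ranges used by the particle-swarm fit: capillary filtration
#' coefficient `Lp` in 0.1-20 mL/min/mmHg, large-pore fraction `alpha_LP`
#' in 0.001-0.150, maximum pump rate `Jp_max` in 0.01-100 mmol/min, and
#' (optionally) the five fitted initial-state multipliers in 0.98-1.02.
#'
#' @param with_multipliers include the five initial-state multiplier
#'   dimensions (plasma volume, total protein, sodium, potassium, urea).
#' @return a two-row matrix (`lower`, `upper`) with named columns.
#' @export
hd_default_bounds <- function(with_multipliers = TRUE) {
  lo <- c(Lp = 0.1, alpha_LP = 0.001, Jp_max = 0.01)
  hi <- c(Lp = 20.0, alpha_LP = 0.150, Jp_max = 100.0)
  if (with_multipliers) {
    m <- c(m_VP = 0.98, m_TP = 0.98, m_Na = 0.98, m_K = 0.98, m_U = 0.98)
    lo <- c(lo, m)
    hi <- c(hi, m + 0.04)
  }
  rbind(lower = lo, upper = hi)
}
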