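#' Ultrafiltration profile
#'
#' Instantaneous ultrafiltration rate at time `t`. In constant mode the
#' treatment value applies from t = 0. In exponential mode the rate rises
#' as `lambda (e^{0.1 t} - 1)` with `lambda` fixed so the treatment value
#' is reached at t = 10 min, and is constant afterwards; the same
#' relative onset factor is applied by the session engine to the
#' dialysances.
#'
#' @param t time since session start (min), within `[0, duration]`.
#' @param patient an [hd_patient()].
#' @return ultrafiltration rate (mL/min).
#' @export
uf_profile <- function(t, patient) {
  if (any(t < 0 | t > patient$duration))
    stop("time outside the session")
  patient$Juf * ramp_factor(t, patient$ramp)
}

# Relative onset factor in [0, 1]; shared by UF and dialysances.
ramp_factor <- function(t, ramp, rate = 0.1, horizon = 10) {
  if (ramp == "none") return(rep(1, length(t)))
  ifelse(t >= horizon, 1, expm1(rate * t) / expm1(rate * horizon))
}

#' Dialyzer solute removal rate
#'
#' Convective plus dialysance-driven diffusive removal,
#' `J_s_d = J_UF(t) C_s_P + D_s (1 - J_UF(t)/Q_b) (C_s_P - C_s_d)`,
#' positive when the solute leaves the body. The flux can be negative
#' (net gain), e.g. for sodium against a 142 mmol/L dialysate.
#'
#' @param solute one of `"na"`, `"k"`, `"urea"`.
#' @param c_P plasma concentration (mmol/L), non-negative.
#' @param t time (min).
#' @param patient an [hd_patient()] carrying flows, dialysances and
#'   dialysate concentrations.
#' @return removal rate (mmol/min).
#' @export
dialyzer_flux <- function(solute = c("na", "k", "urea"), c_P, t, patient) {
  solute <- match.arg(solute)
  if (any(c_P < 0)) stop("plasma concentration must be non-negative")
  if (patient$Qb <= 0) stop("blood flow must be positive")
  rf <- ramp_factor(t, patient$ramp)
  Juf <- patient$Juf * rf
  D <- switch(solute, na = patient$D_na, k = patient$D_k,
              urea = patient$D_urea) * rf
  Cd <- switch(solute, na = patient$Cd_na, k = patient$Cd_k,
               urea = patient$Cd_urea)
  (Juf * c_P + D * (1 - Juf / patient$Qb) * (c_P - Cd)) / 1000
}

#' Total solute mass removed over a session
#'
#' Integral of the dialyzer removal rate over the session. By default the
#' value comes from the cumulative-removal bookkeeping state carried by
#' the integrator (accurate to solver tolerance); `method = "trapezoid"`
#' integrates the flux trajectory on the output grid instead.
#'
#' @param sim an `hd_sim` from [simulate_session()].
#' @param solute `"na"`, `"k"`, `"urea"` or (Expanded variant) `"a"`.
#' @param method `"state"` or `"trapezoid"`.
#' @return removed mass (mmol), positive for net removal.
#' @export
removed_mass <- function(sim, solute = c("na", "k", "urea", "a"),
                         method = c("state", "trapezoid")) {
  solute <- match.arg(solute)
  method <- match.arg(method)
  if (solute == "a" && sim$patient$variant != "expanded")
    stop("solute A exists only in the expanded variant")
  if (method == "state") {
    col <- paste0("Mrem_", solute)
    return(unname(sim$states[nrow(sim$states), col]))
  }
  t <- sim$times
  f <- sim$fluxes[[paste0("Jd_", solute)]]
  sum(diff(t) * (head(f, -1) + tail(f, -1)) / 2)
}
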