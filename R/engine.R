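#' Partition an extracellular solute mass between plasma and interstitium
#'
#' Small solutes equilibrate across the capillary wall essentially
#' instantaneously, with the interstitial concentration held at a
#' constant fraction (`offset`) of the plasma one:
#' `c_P = M / (V_P + offset V_IS)`, `c_IS = offset c_P`. Mass is
#' conserved exactly: `c_P V_P + c_IS V_IS = M`.
#'
#' @param M_EC total extracellular mass (mmol).
#' @param V_P,V_IS plasma and interstitial volumes (L), positive.
#' @param offset interstitial/plasma concentration ratio (0.98 for the
#'   ionic solutes, 1 for urea).
#' @return list with `c_P` and `c_IS` (mmol/L).
#' @export
partition_extracellular <- function(M_EC, V_P, V_IS, offset = 0.98) {
  if (any(V_P <= 0) || any(V_IS <= 0)) stop("volumes must be positive")
  c_P <- M_EC / (V_P + offset * V_IS)
  list(c_P = c_P, c_IS = offset * c_P)
}

solute_names <- function(variant) {
  if (variant == "expanded") c("na", "k", "urea", "a") else c("na", "k", "urea")
}

state_names <- function(variant) {
  sols <- solute_names(variant)
  c("V_P", "V_IS", "V_IC", "M_TP_P", "M_TP_IS",
    as.vector(rbind(paste0("MEC_", sols), paste0("MIC_", sols))),
    paste0("Mrem_", sols), "V_UF")
}

#' Initialize the model at a whole-body steady state
#'
#' Builds the complete parameterisation of one session from the patient
#' record and the three estimated parameters, such that every state
#' derivative is zero at t = 0 with dialysis off:
#' \itemize{
#'   \item interstitial volume `V_IS0 = ECV0 - V_P0` and interstitial
#'     protein at `R0` times the plasma concentration;
#'   \item solute masses from the plasma concentrations, the fixed 2\%
#'     interstitial offsets and the intracellular equilibrium ratios;
#'   \item the initial osmolarity target
#'     `Theta0 = 2 C_Na + 2 C_K + C_Gl + C_U` (plasma values), and the
#'     per-compartment equivalent masses `M_eq` chosen so interstitial
#'     and intracellular osmolarity both equal `Theta0`;
#'   \item ion diffusivities from [calibrate_diffusivities()];
#'   \item capillary pressure `P_c` and baseline lymph flow solved
#'     jointly so that transcapillary fluid filtration equals lymph
#'     return and protein pore leak equals lymph protein return.
#' }
#'
#' @param patient an [hd_patient()].
#' @param Lp capillary filtration coefficient (mL/min/mmHg).
#' @param alpha_LP large-pore fraction of `Lp`.
#' @param Jp_max maximum Na/K pump rate (mmol/min).
#' @param fixed an [hd_fixed_params()] list.
#' @param multipliers optional named vector of fitted initial-state
#'   multipliers (`m_VP`, `m_TP`, `m_Na`, `m_K`, `m_U`), each near 1,
#'   applied to the measured pre-dialysis values before initialization.
#' @return an object of class `hd_model`: the initial state vector,
#'   per-pore table, derived quantities (`P_c`, `Jv_lymph0`, `w_Na`,
#'   `w_K`, `M_eq_IS`, `M_eq_IC`, `B0`, `theta0`) and all inputs.
#' @export
initialize_steady_state <- function(patient, Lp, alpha_LP, Jp_max,
                                    fixed = hd_fixed_params(),
                                    multipliers = NULL) {
  Lp <- unname(Lp); alpha_LP <- unname(alpha_LP); Jp_max <- unname(Jp_max)
  m <- c(m_VP = 1, m_TP = 1, m_Na = 1, m_K = 1, m_U = 1)
  if (!is.null(multipliers)) m[names(multipliers)] <- multipliers
  V_P0 <- patient$V_P0 * m[["m_VP"]]
  tp <- patient$tp_gdl * m[["m_TP"]]
  cNa <- patient$na * m[["m_Na"]]
  cK <- patient$k * m[["m_K"]]
  cU <- patient$urea * m[["m_U"]]
  V_IS0 <- patient$ECV0 - V_P0
  V_IC0 <- patient$ICV0
  if (V_IS0 <= 0) stop("plasma volume exceeds extracellular volume")
  expanded <- patient$variant == "expanded"
  sols <- solute_names(patient$variant)

  # protein (g; concentrations in g/L internally)
  cTP_P <- tp * 10
  cTP_IS <- fixed$R0 * cTP_P
  M_TP_P <- cTP_P * V_P0
  M_TP_IS <- cTP_IS * V_IS0

  # small solutes: extracellular mass from plasma conc + offset,
  # intracellular from the equilibrium ratios
  cNa_IS <- fixed$offset_Na * cNa
  cK_IS <- fixed$offset_K * cK
  cU_IS <- fixed$offset_U * cU
  cNa_IC <- fixed$ratio_Na * cNa
  cK_IC <- fixed$ratio_K * cK
  cU_IC <- fixed$ratio_U * cU
  MEC <- c(na = cNa * (V_P0 + fixed$offset_Na * V_IS0),
           k = cK * (V_P0 + fixed$offset_K * V_IS0),
           urea = cU * (V_P0 + fixed$offset_U * V_IS0))
  MIC <- c(na = cNa_IC * V_IC0, k = cK_IC * V_IC0, urea = cU_IC * V_IC0)
  cA_IS <- 0; cA_IC <- 0; gamma_A <- 1
  if (expanded) {
    cA_P <- fixed$cA_EC0
    cA_IS <- fixed$offset_A * cA_P
    cA_IC <- fixed$cA_IC0
    gamma_A <- cA_IS / cA_IC
    MEC[["a"]] <- cA_P * (V_P0 + fixed$offset_A * V_IS0)
    MIC[["a"]] <- cA_IC * V_IC0
  }

  # osmolarity target and equivalent masses
  theta0 <- 2 * cNa + 2 * cK + patient$glucose + cU
  sum_IS <- cNa_IS + cK_IS + cU_IS + cA_IS + cTP_IS / fixed$MW_protein
  sum_IC <- cNa_IC + cK_IC + cU_IC + cA_IC
  M_eq_IS <- V_IS0 * (theta0 / fixed$osm_coeff - sum_IS)
  M_eq_IC <- V_IC0 * (theta0 / fixed$osm_coeff - sum_IC)
  if (M_eq_IS < 0 || M_eq_IC < 0)
    stop("negative equivalent mass: osmolarity target below described solutes")

  # pump calibration
  B0 <- pump_activation(cK_IS, cNa_IC, fixed)
  w <- if (Jp_max > 0) {
    calibrate_diffusivities(Jp_max, cNa_IS, cNa_IC, cK_IS, cK_IC, fixed)
  } else c(w_Na = 0, w_K = 0)
  w_A <- if (expanded) w[["w_K"]] else 0

  # capillary pressure and lymph baseline from the joint steady state
  pores <- pore_hydraulics(Lp, alpha_LP, fixed)
  Pi_P <- oncotic_pressure(cTP_P / 10)
  Pi_IS <- oncotic_pressure(cTP_IS / 10)
  g <- function(P_c) {
    fl <- capillary_fluid_flux(P_c, fixed$P_IS0, Pi_P, Pi_IS, pores)
    protein_flux(cTP_P, cTP_IS, fl$per_pore, pores) - cTP_IS * fl$total
  }
  P_null <- fixed$P_IS0 + sum(pores$alpha * pores$sigma) * (Pi_P - Pi_IS)
  lo <- P_null
  hi <- P_null + 1
  while (g(hi) > 0 && hi < P_null + 200) hi <- hi + (hi - P_null)
  if (g(hi) > 0)
    stop("failed to bracket capillary pressure: Starling balance g(",
         signif(hi, 4), ") = ", signif(g(hi), 4))
  P_c <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  Jv_lymph0 <- capillary_fluid_flux(P_c, fixed$P_IS0, Pi_P, Pi_IS,
                                    pores)$total
  if (Jv_lymph0 < 0) stop("initialization produced negative lymph flow")

  state0 <- c(V_P0, V_IS0, V_IC0, M_TP_P, M_TP_IS,
              as.vector(rbind(MEC, MIC)),
              rep(0, length(sols)), 0)
  names(state0) <- state_names(patient$variant)

  out <- list(patient = patient, fixed = fixed,
              est = c(Lp = Lp, alpha_LP = alpha_LP, Jp_max = Jp_max),
              multipliers = m, pores = pores,
              state0 = state0, V_IS0 = V_IS0,
              P_c = P_c, Jv_lymph0 = Jv_lymph0,
              w_Na = w[["w_Na"]], w_K = w[["w_K"]], w_A = w_A,
              gamma_A = gamma_A,
              M_eq_IS = M_eq_IS, M_eq_IC = M_eq_IC,
              B0 = B0, theta0 = theta0)
  class(out) <- "hd_model"
  out
}

#' @export
print.hd_model <- function(x, ...) {
  cat(sprintf("<hd_model %s> Lp %.3f mL/min/mmHg, alpha_LP %.4f, Jp_max %.3f mmol/min\n",
              x$patient$id, x$est[["Lp"]], x$est[["alpha_LP"]],
              x$est[["Jp_max"]]))
  cat(sprintf("  derived: P_c %.2f mmHg  Jv_lymph0 %.3f mL/min  w_Na %.1f  w_K %.1f mL/min\n",
              x$P_c, x$Jv_lymph0, x$w_Na, x$w_K))
  cat(sprintf("  M_eq: interstitial %.0f, intracellular %.0f mmol; Theta0 %.1f mmol/L\n",
              x$M_eq_IS, x$M_eq_IC, x$theta0))
  invisible(x)
}

#' Instantaneous flows for a model state
#'
#' Evaluates every fluid and solute flow, pressure and osmolarity at one
#' time point. Fluid flows in mL/min (transcapillary and lymph positive
#' as filtration plasma-to-interstitium and return
#' interstitium-to-plasma respectively; cell-membrane water positive into
#' the cell), protein flows in g/min, solute flows in mmol/min.
#'
#' @param t time (min).
#' @param state named state vector (as in `model$state0`).
#' @param model an `hd_model`.
#' @param dialysis_on logical; `FALSE` evaluates the session with the
#'   dialyzer disconnected.
#' @return named list of flows and auxiliary quantities.
#' @export
flux_snapshot <- function(t, state, model, dialysis_on = TRUE) {
  fx <- model$fixed
  pt <- model$patient
  sols <- solute_names(pt$variant)
  V_P <- state[["V_P"]]; V_IS <- state[["V_IS"]]; V_IC <- state[["V_IC"]]
  cTP_P <- state[["M_TP_P"]] / V_P
  cTP_IS <- state[["M_TP_IS"]] / V_IS
  Pi_P <- oncotic_pressure(cTP_P / 10)
  Pi_IS <- oncotic_pressure(cTP_IS / 10)
  P_IS <- interstitial_pressure(V_IS, model$V_IS0, fx)
  fl <- capillary_fluid_flux(model$P_c, P_IS, Pi_P, Pi_IS, model$pores)
  J_TP_ISP <- protein_flux(cTP_P, cTP_IS, fl$per_pore, model$pores) / 1000
  ly <- lymph_flow(P_IS, cTP_IS, model$Jv_lymph0, fx)

  offs <- c(na = fx$offset_Na, k = fx$offset_K, urea = fx$offset_U,
            a = fx$offset_A)[sols]
  c_P <- c_IS <- c_IC <- numeric(length(sols))
  names(c_P) <- names(c_IS) <- names(c_IC) <- sols
  for (s in sols) {
    pp <- partition_extracellular(state[[paste0("MEC_", s)]], V_P, V_IS,
                                  offs[[s]])
    c_P[[s]] <- pp$c_P
    c_IS[[s]] <- pp$c_IS
    c_IC[[s]] <- state[[paste0("MIC_", s)]] / V_IC
  }
  cA_IS <- if ("a" %in% sols) c_IS[["a"]] else 0
  cA_IC <- if ("a" %in% sols) c_IC[["a"]] else 0
  theta_IS <- osmolarity(c_IS[["na"]], c_IS[["k"]], c_IS[["urea"]],
                         cTP_IS / fx$MW_protein, model$M_eq_IS, V_IS,
                         fx$osm_coeff, cA_IS)
  theta_IC <- osmolarity(c_IC[["na"]], c_IC[["k"]], c_IC[["urea"]],
                         0, model$M_eq_IC, V_IC, fx$osm_coeff, cA_IC)
  Jv_ISIC <- water_flux(theta_IC, theta_IS, fx$k_f) * 1000   # mL/min

  B <- pump_activation(c_IS[["k"]], c_IC[["na"]], fx)
  Js <- c(na = ion_flux("na", c_IS[["na"]], c_IC[["na"]], model$w_Na, B,
                        model$est[["Jp_max"]]),
          k = ion_flux("k", c_IS[["k"]], c_IC[["k"]], model$w_K, B,
                       model$est[["Jp_max"]]),
          urea = urea_flux(c_IS[["urea"]], c_IC[["urea"]], fx$k_U))
  if ("a" %in% sols)
    Js[["a"]] <- soluteA_flux(cA_IS, cA_IC, model$w_A, model$gamma_A)

  if (dialysis_on) {
    Jv_UF <- uf_profile(min(t, pt$duration), pt)
    Jd <- c(na = dialyzer_flux("na", c_P[["na"]], t, pt),
            k = dialyzer_flux("k", c_P[["k"]], t, pt),
            urea = dialyzer_flux("urea", c_P[["urea"]], t, pt))
    if ("a" %in% sols) {
      rf <- ramp_factor(t, pt$ramp)
      Cd_a <- fx$cA_EC0 - (pt$na - pt$Cd_na)
      Jd[["a"]] <- (Jv_UF * c_P[["a"]] +
                      pt$D_na * rf * (1 - Jv_UF / pt$Qb) *
                        (c_P[["a"]] - Cd_a)) / 1000
    }
  } else {
    Jv_UF <- 0
    Jd <- setNames(rep(0, length(sols)), sols)
  }

  c(list(Jv_ISP = fl$total, Jv_L = ly$Jv_L, Jv_ISIC = Jv_ISIC,
         Jv_UF = Jv_UF, J_TP_ISP = J_TP_ISP, J_TP_L = ly$J_TP_L / 1000,
         theta_IS = theta_IS, theta_IC = theta_IC,
         P_IS = P_IS, Pi_P = Pi_P, Pi_IS = Pi_IS, B = B),
    as.list(setNames(fl$per_pore, paste0("Jv_", names(fl$per_pore)))),
    as.list(setNames(Js, paste0("Js_", sols))),
    as.list(setNames(Jd, paste0("Jd_", sols))),
    as.list(setNames(c_P, paste0("cP_", sols))))
}

#' Right-hand side of the session ODE system (reference implementation)
#'
#' Volume and mass balances over the three compartments. Written in
#' plain R; the integrator normally uses the equivalent compiled
#' right-hand side, and the two are cross-checked in the test suite.
#'
#' @inheritParams flux_snapshot
#' @return list whose first element is the derivative vector (native
#'   units per minute) and whose second is the flux snapshot.
#' @export
hd_rhs <- function(t, state, model, dialysis_on = TRUE) {
  f <- flux_snapshot(t, state, model, dialysis_on)
  sols <- solute_names(model$patient$variant)
  dV_P <- (-f$Jv_ISP + f$Jv_L - f$Jv_UF) / 1000
  dV_IS <- (f$Jv_ISP - f$Jv_L - f$Jv_ISIC) / 1000
  dV_IC <- f$Jv_ISIC / 1000
  dM_TP_P <- -f$J_TP_ISP + f$J_TP_L
  dM_TP_IS <- f$J_TP_ISP - f$J_TP_L
  d <- c(dV_P, dV_IS, dV_IC, dM_TP_P, dM_TP_IS)
  for (s in sols) {
    Js <- f[[paste0("Js_", s)]]
    Jd <- f[[paste0("Jd_", s)]]
    d <- c(d, -Js - Jd, Js)
  }
  d <- c(d, unlist(f[paste0("Jd_", sols)], use.names = FALSE),
         f$Jv_UF / 1000)
  names(d) <- state_names(model$patient$variant)
  list(d, f)
}

pack_parms <- function(model, dialysis_on = TRUE) {
  fx <- model$fixed
  pt <- model$patient
  expanded <- pt$variant == "expanded"
  w <- c(model$w_Na, model$w_K, fx$k_U, model$w_A) / 1000
  offs <- c(fx$offset_Na, fx$offset_K, fx$offset_U, fx$offset_A)
  D <- c(pt$D_na, pt$D_k, pt$D_urea, if (expanded) pt$D_na else 0) / 1000
  Cd_a <- fx$cA_EC0 - (pt$na - pt$Cd_na)
  Cd <- c(pt$Cd_na, pt$Cd_k, pt$Cd_urea, if (expanded) Cd_a else 0)
  if (!dialysis_on) D <- rep(0, 4)
  c(model$est[["Lp"]] / 1000,
    model$pores$alpha, model$pores$sigma, model$pores$PS / 1000,
    model$P_c, fx$P_IS0, model$V_IS0, fx$compliance, fx$LS,
    model$Jv_lymph0 / 1000, fx$k_f, fx$osm_coeff, fx$MW_protein,
    model$est[["Jp_max"]], fx$Ch_Na, fx$Ch_K, -3, 2,
    if (expanded) 4 else 3,
    pt$Qb / 1000, if (dialysis_on) pt$Juf / 1000 else 0,
    if (pt$ramp == "exponential") 1 else 0, 0.1, 10,
    model$gamma_A, w, offs, D, Cd, model$M_eq_IS, model$M_eq_IC)
}

#' Simulate a full dialysis session
#'
#' Initializes the steady state and integrates the session ODE system
#' with a stiff adaptive solver (lsoda), reporting states and every
#' instantaneous flow on a uniform output grid. Cumulative
#' dialyzer-removed mass per solute and cumulative ultrafiltrate volume
#' are carried as additional integrated states so conservation checks
#' hold to solver tolerance.
#'
#' @inheritParams initialize_steady_state
#' @param dt output grid spacing (min).
#' @param rtol,atol solver tolerances; `atol` defaults to `1e-8` scaled
#'   by each state's initial magnitude.
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`.
#' @param dialysis_on `FALSE` leaves the dialyzer disconnected (used for
#'   steady-state verification).
#' @param fluxes compute the flux trajectory on the output grid.
#' @param model optional pre-built `hd_model` (skips initialization).
#' @param times optional explicit output grid (min), starting at 0;
#'   overrides `dt`.
#' @return an object of class `hd_sim`: `times`, `states` (matrix, one
#'   row per grid point), `fluxes` (data.frame), and the `hd_model`.
#' @export
simulate_session <- function(patient, Lp, alpha_LP, Jp_max,
                             fixed = hd_fixed_params(),
                             multipliers = NULL, dt = 1,
                             rtol = 1e-8, atol = NULL,
                             engine = c("compiled", "R"),
                             dialysis_on = TRUE, fluxes = TRUE,
                             model = NULL, times = NULL) {
  engine <- match.arg(engine)
  if (is.null(model))
    model <- initialize_steady_state(patient, Lp, alpha_LP, Jp_max,
                                     fixed, multipliers)
  y0 <- model$state0
  if (is.null(times))
    times <- unique(c(seq(0, model$patient$duration, by = dt),
                      model$patient$duration))
  if (is.null(atol)) atol <- 1e-8 * pmax(abs(y0), 1)
  if (engine == "compiled") {
    out <- deSolve::lsoda(y = y0, times = times, func = "hd_derivs",
                          parms = pack_parms(model, dialysis_on),
                          dllname = "hdkin", initfunc = "hd_init",
                          rtol = rtol, atol = atol)
  } else {
    out <- deSolve::lsoda(y = y0, times = times,
                          func = function(t, y, p) {
                            names(y) <- names(y0)
                            list(hd_rhs(t, y, model, dialysis_on)[[1]])
                          },
                          parms = NULL, rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0)
    stop("solver failed at t = ", max(out[, 1]))
  states <- out[, -1, drop = FALSE]
  colnames(states) <- names(y0)
  fx_df <- NULL
  if (fluxes) {
    rows <- lapply(seq_along(times), function(i)
      flux_snapshot(times[i], states[i, ], model, dialysis_on))
    fx_df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, optional = TRUE)))
  }
  res <- list(times = times, states = states, fluxes = fx_df,
              model = model, patient = model$patient,
              est = model$est, dialysis_on = dialysis_on)
  class(res) <- "hd_sim"
  res
}

#' @export
print.hd_sim <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("<hd_sim %s (%s)> %d output points over %.0f min\n",
              x$patient$id, x$patient$variant, n, max(x$times)))
  cat(sprintf("  plasma volume %.3f -> %.3f L; total body water change %.3f L\n",
              x$states[1, "V_P"], x$states[n, "V_P"],
              sum(x$states[n, c("V_P", "V_IS", "V_IC")]) -
                sum(x$states[1, c("V_P", "V_IS", "V_IC")])))
  invisible(x)
}

#' Fitted observables along a simulated session
#'
#' The five quantities compared against clinical measurements: plasma
#' volume and the plasma concentrations of total protein, sodium,
#' potassium and urea.
#'
#' @param sim an `hd_sim`.
#' @param times optional times (min) within the simulated span; times
#'   between grid points are linearly interpolated.
#' @return data.frame with columns `time`, `pv` (L), `tp` (g/dL), `na`,
#'   `k`, `urea` (mmol/L).
#' @export
session_observables <- function(sim, times = NULL) {
  fx <- sim$model$fixed
  at <- function(st) {
    ob <- data.frame(pv = st[, "V_P"],
                     tp = st[, "M_TP_P"] / st[, "V_P"] / 10)
    for (s in c("na", "k", "urea")) {
      off <- switch(s, na = fx$offset_Na, k = fx$offset_K,
                    urea = fx$offset_U)
      ob[[s]] <- st[, paste0("MEC_", s)] /
        (st[, "V_P"] + off * st[, "V_IS"])
    }
    ob
  }
  if (is.null(times)) return(cbind(time = sim$times, at(sim$states)))
  if (any(times < min(sim$times) - 1e-9 | times > max(sim$times) + 1e-9))
    stop("requested times outside the output grid")
  full <- at(sim$states)
  ob <- data.frame(time = times)
  for (v in names(full))
    ob[[v]] <- stats::approx(sim$times, full[[v]], xout = times)$y
  ob
}
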