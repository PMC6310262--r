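#' Relative root-mean-squared error between simulation and observations
#'
#' `RMSE = sqrt( (1/N) sum_Y sum_i [(Y_i_sim - Y_i_obs)/Y_i_obs]^2 )`
#' over the five fitted variables (plasma volume, total protein, sodium,
#' potassium, urea concentrations) and their sampled time points.
#' Relative errors are squared inside the sums, so errors of opposite
#' sign cannot cancel.
#'
#' @param sim an `hd_sim` whose output grid covers the observation times.
#' @param obs an observation data.frame (`time`, `variable`, `value`)
#'   as produced by [make_observations()].
#' @return non-negative scalar; attribute `per_variable` carries the
#'   per-variable RMSE breakdown.
#' @export
rmse_objective <- function(sim, obs) {
  if (any(obs$value == 0)) stop("zero observed value: relative error undefined")
  so <- session_observables(sim, times = sort(unique(obs$time)))
  rel2 <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    y_sim <- so[so$time == obs$time[i], obs$variable[i]]
    rel2[i] <- ((y_sim - obs$value[i]) / obs$value[i])^2
  }
  out <- sqrt(mean(rel2))
  pv <- sqrt(tapply(rel2, obs$variable, mean))
  attr(out, "per_variable") <- pv
  out
}

objective_for <- function(patient, obs, fixed, variant_override = NULL,
                          rtol = 1e-6) {
  pt <- patient
  if (!is.null(variant_override)) pt$variant <- variant_override
  obs_times <- sort(unique(obs$time))
  function(x) {
    mult <- if (length(x) > 3) x[4:8] else NULL
    if (!is.null(mult))
      names(mult) <- c("m_VP", "m_TP", "m_Na", "m_K", "m_U")
    val <- tryCatch({
      sim <- simulate_session(pt, Lp = x[1], alpha_LP = x[2],
                              Jp_max = x[3], fixed = fixed,
                              multipliers = mult,
                              times = union(0, obs_times),
                              rtol = rtol, fluxes = FALSE)
      as.numeric(rmse_objective(sim, obs))
    }, error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }
}

#' Particle-swarm estimation of the session transport parameters
#'
#' Fits `(Lp, alpha_LP, Jp_max)` and, by default, five initial-state
#' multipliers (plasma volume and the four plasma concentrations, each
#' within +/- 2 percent of the measured value) by global-best particle
#' swarm minimisation of [rmse_objective()]. The swarm uses constriction
#' coefficients (inertia 0.729, cognitive = social = 1.49445) and
#' reflective bound handling; runs are deterministic for a fixed seed.
#'
#' @param patient an [hd_patient()].
#' @param obs observation data.frame (`time`, `variable`, `value`).
#' @param bounds two-row matrix from [hd_default_bounds()].
#' @param fixed an [hd_fixed_params()] list.
#' @param n_particles,n_iter swarm size and iteration count.
#' @param seed integer seed for the swarm's random draws.
#' @param rtol solver relative tolerance used inside the objective.
#' @param variant optionally refit under the other model variant (e.g.
#'   `"expanded"`) regardless of the patient record's own setting.
#' @return an object of class `hd_fit`: estimated parameters,
#'   multipliers, objective value, per-variable RMSE, and swarm
#'   diagnostics.
#' @export
pso_fit <- function(patient, obs, bounds = hd_default_bounds(),
                    fixed = hd_fixed_params(),
                    n_particles = 30, n_iter = 200, seed = 1,
                    rtol = 1e-6, variant = NULL) {
  lo <- bounds["lower", ]; hi <- bounds["upper", ]
  d <- length(lo)
  f <- objective_for(patient, obs, fixed, variant, rtol)
  set.seed(seed)
  X <- matrix(0, n_particles, d)
  for (j in seq_len(d)) X[, j] <- runif(n_particles, lo[j], hi[j])
  V <- matrix(0, n_particles, d)
  for (j in seq_len(d))
    V[, j] <- runif(n_particles, -(hi[j] - lo[j]), hi[j] - lo[j]) * 0.1
  fX <- apply(X, 1, f)
  n_fail <- sum(!is.finite(fX))
  if (all(!is.finite(fX)))
    stop("all initial particles failed simulation (", n_fail, " failures)")
  Pb <- X; fPb <- fX
  g <- which.min(fPb)
  Gb <- Pb[g, ]; fGb <- fPb[g]
  w <- 0.729; c1 <- 1.49445; c2 <- 1.49445
  for (it in seq_len(n_iter)) {
    r1 <- matrix(runif(n_particles * d), n_particles, d)
    r2 <- matrix(runif(n_particles * d), n_particles, d)
    V <- w * V + c1 * r1 * (Pb - X) +
      c2 * r2 * (matrix(Gb, n_particles, d, byrow = TRUE) - X)
    X <- X + V
    for (j in seq_len(d)) {    # reflective bounds
      below <- X[, j] < lo[j]
      X[below, j] <- pmin(hi[j], 2 * lo[j] - X[below, j])
      V[below, j] <- -V[below, j]
      above <- X[, j] > hi[j]
      X[above, j] <- pmax(lo[j], 2 * hi[j] - X[above, j])
      V[above, j] <- -V[above, j]
    }
    fX <- apply(X, 1, f)
    n_fail <- n_fail + sum(!is.finite(fX))
    imp <- fX < fPb
    Pb[imp, ] <- X[imp, ]; fPb[imp] <- fX[imp]
    g <- which.min(fPb)
    if (fPb[g] < fGb) { Gb <- Pb[g, ]; fGb <- fPb[g] }
  }
  est <- setNames(Gb[1:3], c("Lp", "alpha_LP", "Jp_max"))
  mult <- if (d > 3)
    setNames(Gb[4:8], c("m_VP", "m_TP", "m_Na", "m_K", "m_U")) else NULL
  # per-variable breakdown at the optimum
  pt <- patient
  if (!is.null(variant)) pt$variant <- variant
  sim <- simulate_session(pt, est[["Lp"]], est[["alpha_LP"]],
                          est[["Jp_max"]], fixed = fixed,
                          multipliers = mult, rtol = rtol, fluxes = FALSE,
                          times = union(0, sort(unique(obs$time))))
  obj <- rmse_objective(sim, obs)
  out <- list(est = est, multipliers = mult,
              objective = as.numeric(obj),
              per_variable = attr(obj, "per_variable"),
              variant = pt$variant, bounds = bounds,
              n_particles = n_particles, n_iter = n_iter, seed = seed,
              n_failed_evals = n_fail, patient_id = patient$id)
  class(out) <- "hd_fit"
  out
}

#' @export
print.hd_fit <- function(x, ...) {
  cat(sprintf("<hd_fit %s (%s)> RMSE %.4f\n", x$patient_id, x$variant,
              x$objective))
  cat(sprintf("  Lp %.3f mL/min/mmHg  alpha_LP %.4f  Jp_max %.3f mmol/min\n",
              x$est[["Lp"]], x$est[["alpha_LP"]], x$est[["Jp_max"]]))
  invisible(x)
}

#' Fit a cohort of sessions and summarise the estimates
#'
#' Runs [pso_fit()] per session, collecting the per-session estimates
#' and the cohort median and quartiles of each parameter. Per-session
#' failures are recorded and skipped rather than aborting the cohort.
#'
#' @param sessions list of [hd_patient()] records.
#' @param obs_list list of observation data.frames, parallel to
#'   `sessions`.
#' @param seed base seed; session `i` uses `seed + i`.
#' @param ... passed to [pso_fit()] (swarm budget, bounds, variant, ...).
#' @return list with `fits` (per-session `hd_fit` or error message),
#'   `table` (one row per successful session) and `summary` (median, Q1,
#'   Q3 per parameter).
#' @export
fit_cohort <- function(sessions, obs_list, seed = 1, ...) {
  stopifnot(length(sessions) == length(obs_list), length(sessions) >= 1)
  fits <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    fits[[i]] <- tryCatch(
      pso_fit(sessions[[i]], obs_list[[i]], seed = seed + i, ...),
      error = function(e) conditionMessage(e))
  }
  ok <- vapply(fits, inherits, logical(1), "hd_fit")
  tab <- do.call(rbind, lapply(fits[ok], function(f)
    data.frame(id = f$patient_id, variant = f$variant,
               Lp = f$est[["Lp"]], alpha_LP = f$est[["alpha_LP"]],
               Jp_max = f$est[["Jp_max"]], objective = f$objective)))
  summ <- NULL
  if (!is.null(tab)) {
    qs <- function(v) c(median = median(v), q1 = unname(quantile(v, 0.25)),
                        q3 = unname(quantile(v, 0.75)))
    summ <- rbind(Lp = qs(tab$Lp), alpha_LP = qs(tab$alpha_LP),
                  Jp_max = qs(tab$Jp_max))
  }
  list(fits = fits, table = tab, summary = summ, n_failed = sum(!ok))
}
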