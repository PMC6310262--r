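#' Read and write per-session patient files
#'
#' Patient sessions are stored as flat JSON with the exact field names
#' of [hd_patient()]; unknown keys are rejected. Units are fixed by the
#' schema (L, mL/min, mmHg, mmol/L, g/dL, min) and never inferred.
#'
#' @param path file path.
#' @return [read_patient()] returns an `hd_patient`.
#' @export
read_patient <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(hd_patient))
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown keys in ", path, ": ", paste(extra, collapse = ", "))
  do.call(hd_patient, x)
}

#' @rdname read_patient
#' @param patient an [hd_patient()].
#' @export
write_patient <- function(patient, path) {
  x <- unclass(patient)
  jsonlite::write_json(x[!vapply(x, function(v) is.na(v[1]), logical(1))],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an observation CSV
#'
#' Expected columns: `time` (min), `variable` (`pv`, `tp`, `na`, `k`,
#' `urea`), `value`, and optionally `sd`.
#'
#' @param path file path.
#' @param require_all require all five fitted variables to be present.
#' @return data.frame.
#' @export
read_observations <- function(path, require_all = TRUE) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "variable", "value")
  if (!all(need %in% names(obs)))
    stop("observations file must have columns: ", paste(need, collapse = ", "))
  if (require_all) {
    missing <- setdiff(c("pv", "tp", "na", "k", "urea"),
                       unique(obs$variable))
    if (length(missing))
      stop("missing observation variable(s): ",
           paste(missing, collapse = ", "))
  }
  obs
}

#' Write a simulated session as tidy CSV plus a metadata sidecar
#'
#' One row per output time with all states, plasma observables and
#' instantaneous flows; the sidecar (`<path>.meta.json`) records the
#' estimated parameters, derived initialization quantities, solver
#' settings and package version.
#'
#' @param sim an `hd_sim`.
#' @param path CSV destination.
#' @param seed optional seed to record in the sidecar.
#' @return invisibly, `path`.
#' @export
write_sim_csv <- function(sim, path, seed = NULL) {
  df <- data.frame(time = sim$times, sim$states, check.names = FALSE)
  ob <- session_observables(sim)
  df$tp_gdl <- ob$tp
  df$cP_na <- ob$na; df$cP_k <- ob$k; df$cP_urea <- ob$urea
  if (!is.null(sim$fluxes))
    df <- cbind(df, sim$fluxes[setdiff(names(sim$fluxes),
                                       names(df))])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(patient = sim$patient$id, variant = sim$patient$variant,
               est = as.list(sim$est),
               derived = list(P_c = sim$model$P_c,
                              Jv_lymph0 = sim$model$Jv_lymph0,
                              w_Na = sim$model$w_Na, w_K = sim$model$w_K,
                              M_eq_IS = sim$model$M_eq_IS,
                              M_eq_IC = sim$model$M_eq_IC,
                              theta0 = sim$model$theta0),
               dialysis_on = sim$dialysis_on,
               seed = seed,
               package_version = as.character(utils::packageVersion("hdkin")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a fit result as JSON
#'
#' @param fit an `hd_fit` from [pso_fit()].
#' @param path destination.
#' @return invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(patient = fit$patient_id, variant = fit$variant,
            est = as.list(fit$est),
            multipliers = as.list(fit$multipliers),
            objective = fit$objective,
            per_variable_rmse = as.list(fit$per_variable),
            bounds = list(lower = as.list(fit$bounds["lower", ]),
                          upper = as.list(fit$bounds["upper", ])),
            pso = list(n_particles = fit$n_particles, n_iter = fit$n_iter,
                       seed = fit$seed,
                       n_failed_evals = fit$n_failed_evals))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a population specification file
#'
#' JSON with a `session` tag, a `quantities` table (`name`, `median`,
#' `q1`, `q3`) and a `noise` object; missing entries fall back to the
#' built-in defaults of [hd_population_spec()].
#'
#' @param path file path.
#' @return an `hd_popspec`.
#' @export
read_population_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  session <- if (is.null(x$session)) "hd1" else x$session
  overrides <- NULL
  if (!is.null(x$quantities)) {
    overrides <- lapply(seq_len(nrow(x$quantities)), function(i)
      as.list(x$quantities[i, c("median", "q1", "q3")]))
    names(overrides) <- x$quantities$name
  }
  if (!is.null(x$noise)) overrides$noise <- unlist(x$noise)
  hd_population_spec(session, overrides)
}

#' @rdname read_population_spec
#' @param spec an `hd_popspec`.
#' @export
write_population_spec <- function(spec, path) {
  jsonlite::write_json(list(session = spec$session,
                            quantities = spec$quantities,
                            noise = as.list(spec$noise)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run-configuration file
#'
#' Flat JSON controlling solver tolerances, the swarm budget, seeds and
#' the model variant; unknown keys are rejected before any computation.
#'
#' @param path file path, or `NULL` for all defaults.
#' @return named list with fields `variant`, `rtol`, `n_particles`,
#'   `n_iter`, `seed`, `dt`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(variant = "baseline", rtol = 1e-8,
                   n_particles = 30, n_iter = 200, seed = 1, dt = 1)
  if (is.null(path)) return(defaults)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(x), names(defaults))
  if (length(extra))
    stop("unknown configuration keys: ", paste(extra, collapse = ", "))
  if (!is.null(x$variant) &&
      !x$variant %in% c("baseline", "expanded"))
    stop("variant must be 'baseline' or 'expanded'")
  modifyList(defaults, x)
}
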