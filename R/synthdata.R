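#' Population specification for the virtual cohort
#'
#' Median and quartiles per session quantity, defaulting to the
#' published HD1 (first weekly session) or HD3 cohort columns, plus the
#' measurement-noise model per fitted observable: additive Gaussian with
#' sd 0.05 L for plasma volume, 0.2 g/dL for total protein and
#' 0.2 mmol/L for sodium, potassium and urea.
#'
#' @param session `"hd1"` or `"hd3"` default column.
#' @param overrides named list; each element `list(median =, q1 =, q3 =)`
#'   replaces the corresponding quantity, and `noise` (named numeric)
#'   replaces noise sds.
#' @return list of class `hd_popspec` with `quantities` (data.frame:
#'   `name`, `median`, `q1`, `q3`) and `noise` (named numeric sds).
#' @export
hd_population_spec <- function(session = c("hd1", "hd3"),
                               overrides = NULL) {
  session <- match.arg(session)
  q <- if (session == "hd1") rbind(
    data.frame(name = "duration", median = 238,  q1 = 234,  q3 = 247),
    data.frame(name = "Qb",       median = 265,  q1 = 230,  q3 = 320),
    data.frame(name = "Juf",      median = 11.5, q1 = 9.6,  q3 = 13.6),
    data.frame(name = "ECV0",     median = 16.3, q1 = 14.4, q3 = 19.3),
    data.frame(name = "ICV0",     median = 14.5, q1 = 12.1, q3 = 17.0),
    data.frame(name = "V_P0",     median = 3.2,  q1 = 2.8,  q3 = 3.4),
    data.frame(name = "MAP",      median = 93.0, q1 = 79.9, q3 = 110.5),
    data.frame(name = "tp_gdl",   median = 6.5,  q1 = 6.2,  q3 = 6.7),
    data.frame(name = "na",       median = 140.0, q1 = 138.5, q3 = 142.5),
    data.frame(name = "k",        median = 5.6,  q1 = 5.4,  q3 = 6.1),
    data.frame(name = "glucose",  median = 4.7,  q1 = 4.0,  q3 = 5.9),
    data.frame(name = "urea",     median = 55.2, q1 = 44.9, q3 = 67.6),
    data.frame(name = "D_urea",   median = 220.9, q1 = 139.6, q3 = 232.4),
    data.frame(name = "D_k",      median = 153.7, q1 = 129.5, q3 = 176.5),
    data.frame(name = "Cd_na",    median = 142.0, q1 = 140.8, q3 = 144.0),
    data.frame(name = "Cd_k",     median = 3.0,  q1 = 2.1,  q3 = 3.1)
  ) else rbind(
    data.frame(name = "duration", median = 240,  q1 = 236,  q3 = 253),
    data.frame(name = "Qb",       median = 280,  q1 = 240,  q3 = 320),
    data.frame(name = "Juf",      median = 9.2,  q1 = 6.7,  q3 = 10.0),
    data.frame(name = "ECV0",     median = 15.5, q1 = 13.4, q3 = 17.5),
    data.frame(name = "ICV0",     median = 15.0, q1 = 11.8, q3 = 17.9),
    data.frame(name = "V_P0",     median = 3.0,  q1 = 2.6,  q3 = 3.3),
    data.frame(name = "MAP",      median = 90.3, q1 = 80.7, q3 = 99.0),
    data.frame(name = "tp_gdl",   median = 6.6,  q1 = 6.4,  q3 = 6.8),
    data.frame(name = "na",       median = 140.0, q1 = 137.0, q3 = 142.0),
    data.frame(name = "k",        median = 5.4,  q1 = 5.1,  q3 = 6.1),
    data.frame(name = "glucose",  median = 4.7,  q1 = 4.0,  q3 = 5.5),
    data.frame(name = "urea",     median = 46.2, q1 = 38.7, q3 = 52.1),
    data.frame(name = "D_urea",   median = 201.3, q1 = 195.5, q3 = 226.4),
    data.frame(name = "D_k",      median = 146.9, q1 = 120.7, q3 = 169.2),
    data.frame(name = "Cd_na",    median = 142.0, q1 = 141.0, q3 = 143.0),
    data.frame(name = "Cd_k",     median = 2.9,  q1 = 2.1,  q3 = 3.1)
  )
  noise <- c(pv = 0.05, tp = 0.2, na = 0.2, k = 0.2, urea = 0.2)
  if (!is.null(overrides)) {
    for (nm in setdiff(names(overrides), "noise")) {
      i <- match(nm, q$name)
      if (is.na(i)) stop("unknown quantity in overrides: ", nm)
      o <- overrides[[nm]]
      q[i, c("median", "q1", "q3")] <- c(o$median, o$q1, o$q3)
    }
    if (!is.null(overrides$noise))
      noise[names(overrides$noise)] <- overrides$noise
  }
  if (any(q$q1 >= q$q3) || any(q$median < q$q1) || any(q$median > q$q3))
    stop("population spec requires q1 < q3 and median within (q1, q3)")
  out <- list(session = session, quantities = q, noise = noise)
  class(out) <- "hd_popspec"
  out
}

#' Draw one virtual patient from a population specification
#'
#' Each quantity is drawn independently from a log-normal distribution
#' matched to the spec's median and interquartile range (`mu =
#' log(median)`, `sigma = log(q3/q1) / (2 z_0.75)`), with rejection until
#' the consistency constraints hold (`ECV0 > V_P0 + 1` L so that an
#' interstitium exists, `Juf < Qb`). Deterministic for a fixed seed.
#'
#' @param spec an [hd_population_spec()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param median_patient if `TRUE`, no sampling: every quantity at its
#'   spec median.
#' @param variant,ramp passed to [hd_patient()].
#' @param id patient identifier.
#' @return an [hd_patient()].
#' @export
sample_patient <- function(spec = hd_population_spec(), seed = NULL,
                           median_patient = FALSE,
                           variant = "baseline", ramp = "none",
                           id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- spec$quantities
  z75 <- stats::qnorm(0.75)
  draw <- function() {
    v <- setNames(numeric(nrow(q)), q$name)
    for (i in seq_len(nrow(q))) {
      if (median_patient) { v[i] <- q$median[i]; next }
      sdlog <- log(q$q3[i] / q$q1[i]) / (2 * z75)
      v[i] <- rlnorm(1, meanlog = log(q$median[i]), sdlog = sdlog)
    }
    v
  }
  for (attempt in 1:1000) {
    v <- draw()
    if (v[["ECV0"]] > v[["V_P0"]] + 1 && v[["Juf"]] < v[["Qb"]]) break
    if (attempt == 1000) stop("could not draw a consistent patient")
  }
  hd_patient(id = if (is.null(id)) sprintf("virtual-%s", spec$session) else id,
             V_P0 = v[["V_P0"]], ECV0 = v[["ECV0"]], ICV0 = v[["ICV0"]],
             tp_gdl = v[["tp_gdl"]], na = v[["na"]], k = v[["k"]],
             urea = v[["urea"]], glucose = v[["glucose"]],
             MAP = v[["MAP"]],
             duration = v[["duration"]], Qb = v[["Qb"]], Juf = v[["Juf"]],
             D_k = v[["D_k"]], D_urea = v[["D_urea"]],
             Cd_na = v[["Cd_na"]], Cd_k = v[["Cd_k"]], Cd_urea = 0,
             ramp = ramp, variant = variant)
}

#' Hourly observation schedule for a session
#'
#' Five equally spaced sampling times including the session start and
#' end (`t_i = i T / 4`), the schedule on which the fitting error is
#' evaluated.
#'
#' @param duration session length (min).
#' @param n_points number of samples.
#' @return numeric vector of times (min).
#' @export
observation_schedule <- function(duration, n_points = 5) {
  seq(0, duration, length.out = n_points)
}

#' Sample noisy observations from a simulated session
#'
#' Samples the five fitted observables at the schedule times and adds
#' independent Gaussian measurement noise per variable; `sd = 0`
#' reproduces the simulation exactly. Values are truncated at zero from
#' below (a concentration assay cannot report a negative value).
#'
#' @param sim an `hd_sim` whose grid covers the schedule.
#' @param noise named sds per variable (`pv`, `tp`, `na`, `k`, `urea`)
#'   in the observable's own unit; see [hd_population_spec()].
#' @param schedule sampling times (min); default the 5-point hourly
#'   schedule scaled to the session.
#' @param seed integer seed, or `NULL`.
#' @return data.frame (`time`, `variable`, `value`, `sd`).
#' @export
make_observations <- function(sim,
                              noise = hd_population_spec()$noise,
                              schedule = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule))
    schedule <- observation_schedule(sim$patient$duration)
  if (any(schedule < 0) || any(schedule > max(sim$times) + 1e-9))
    stop("schedule outside the simulated span")
  so <- session_observables(sim, times = schedule)
  vars <- c("pv", "tp", "na", "k", "urea")
  out <- do.call(rbind, lapply(vars, function(v) {
    sd_v <- if (v %in% names(noise)) noise[[v]] else 0
    data.frame(time = so$time, variable = v,
               value = pmax(0, so[[v]] + rnorm(nrow(so), 0, sd_v)),
               sd = sd_v)
  }))
  rownames(out) <- NULL
  out
}

#' Write a reproducible synthetic cohort to disk
#'
#' Samples `n` virtual patients, simulates each at the common true
#' parameters, samples noisy observations, and writes one patient JSON
#' and one observation CSV per session plus a truth manifest. The
#' standard test fixture is `n = 23` (the study's cohort size) at the
#' HD1 population settings.
#'
#' @param n cohort size.
#' @param truth named vector `c(Lp =, alpha_LP =, Jp_max =)` generating
#'   the data.
#' @param out_dir destination directory (created if missing).
#' @param seed base seed; patient `i` uses `seed + i` for sampling and
#'   `seed + 10000 + i` for noise.
#' @param spec an [hd_population_spec()].
#' @param noise named sds (see [make_observations()]); pass 0s for
#'   noise-free fixtures.
#' @param variant model variant used for generation.
#' @param fixed an [hd_fixed_params()] list.
#' @return invisibly, a list with the patients, observation tables and
#'   the manifest path.
#' @export
make_fixture_cohort <- function(n, truth, out_dir, seed = 42,
                                spec = hd_population_spec(),
                                noise = hd_population_spec()$noise,
                                variant = "baseline",
                                fixed = hd_fixed_params()) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  patients <- vector("list", n)
  obs_list <- vector("list", n)
  for (i in seq_len(n)) {
    pt <- sample_patient(spec, seed = seed + i, variant = variant,
                         id = sprintf("synthetic-%03d", i))
    sim <- simulate_session(pt, truth[["Lp"]], truth[["alpha_LP"]],
                            truth[["Jp_max"]], fixed = fixed,
                            times = union(0, observation_schedule(pt$duration)),
                            fluxes = FALSE)
    obs <- make_observations(sim, noise = noise, seed = seed + 10000 + i)
    patients[[i]] <- pt
    obs_list[[i]] <- obs
    write_patient(pt, file.path(out_dir, sprintf("patient-%03d.json", i)))
    utils::write.csv(obs,
                     file.path(out_dir, sprintf("observations-%03d.csv", i)),
                     row.names = FALSE)
  }
  manifest <- list(n = n, seed = seed, variant = variant,
                   truth = as.list(truth),
                   noise = as.list(noise),
                   population = spec$session)
  manifest_path <- file.path(out_dir, "truth-manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(patients = patients, observations = obs_list,
                 manifest = manifest_path))
}
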