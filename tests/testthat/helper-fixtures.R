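# Shared fixtures, built once per test run. The cohort-median session
# with the cohort-median estimated parameters is the reference scenario
# used across suites.

median_est <- c(Lp = 11.63, alpha_LP = 0.056, Jp_max = 5.52)

.fixture_env <- new.env()

median_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- initialize_steady_state(
      hd_median_patient(), median_est[["Lp"]], median_est[["alpha_LP"]],
      median_est[["Jp_max"]])
  .fixture_env$model
}

median_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_session(
      hd_median_patient(), median_est[["Lp"]], median_est[["alpha_LP"]],
      median_est[["Jp_max"]])
  .fixture_env$sim
}

# noise-free observations of the median session at the hourly schedule
median_obs_noisefree <- function() {
  if (is.null(.fixture_env$obs0)) {
    pt <- hd_median_patient()
    sim <- simulate_session(pt, median_est[["Lp"]],
                            median_est[["alpha_LP"]],
                            median_est[["Jp_max"]],
                            times = union(0, observation_schedule(pt$duration)),
                            fluxes = FALSE)
    .fixture_env$obs0 <- make_observations(
      sim, noise = c(pv = 0, tp = 0, na = 0, k = 0, urea = 0))
  }
  .fixture_env$obs0
}

random_state <- function(model, seed) {
  set.seed(seed)
  s <- model$state0
  n_dyn <- length(s) - length(solute_names_of(model)) - 1
  s[1:n_dyn] <- s[1:n_dyn] * runif(n_dyn, 0.85, 1.15)
  s
}

solute_names_of <- function(model) {
  if (model$patient$variant == "expanded") c("na", "k", "urea", "a")
  else c("na", "k", "urea")
}
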