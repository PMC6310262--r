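test_that("population spec validates its quantile structure", {
  spec <- hd_population_spec()
  expect_true(all(spec$quantities$q1 < spec$quantities$q3))
  expect_error(hd_population_spec(overrides = list(
    na = list(median = 140, q1 = 145, q3 = 142))), "q1 < q3")
  expect_error(hd_population_spec(overrides = list(
    nonsense = list(median = 1, q1 = 0, q3 = 2))), "unknown quantity")
  s3 <- hd_population_spec("hd3")
  expect_equal(s3$quantities$median[s3$quantities$name == "urea"], 46.2)
})

test_that("patient sampling is seeded, consistent, and median-faithful", {
  p1 <- sample_patient(seed = 7)
  p2 <- sample_patient(seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_patient(seed = 8)))
  # the no-sampling mode reproduces the published median column exactly
  pm <- sample_patient(median_patient = TRUE)
  ref <- hd_median_patient()
  for (f in c("V_P0", "ECV0", "ICV0", "tp_gdl", "na", "k", "urea",
              "glucose", "Qb", "Juf", "D_k", "D_urea", "Cd_na", "Cd_k"))
    expect_equal(pm[[f]], ref[[f]])
  # invariants hold across draws
  for (i in 1:100) {
    p <- sample_patient(seed = 200 + i)
    expect_gt(p$ECV0, p$V_P0)
    expect_lt(p$Juf, p$Qb)
    expect_gt(p$ICV0, 0)
  }
})

test_that("large cohorts reproduce the spec medians", {
  spec <- hd_population_spec()
  set.seed(123)
  draws <- replicate(4000, {
    p <- sample_patient(spec)
    c(p$na, p$urea, p$ECV0, p$Juf)
  })
  med <- apply(draws, 1, median)
  ref <- spec$quantities
  expect_equal(med[1], ref$median[ref$name == "na"], tolerance = 0.02)
  expect_equal(med[2], ref$median[ref$name == "urea"], tolerance = 0.02)
  expect_equal(med[3], ref$median[ref$name == "ECV0"], tolerance = 0.02)
  expect_equal(med[4], ref$median[ref$name == "Juf"], tolerance = 0.02)
})

test_that("observation sampling reproduces the schedule, the noise model
           and seed determinism", {
  sim <- median_sim()
  obs0 <- make_observations(sim, noise = c(pv = 0, tp = 0, na = 0,
                                           k = 0, urea = 0))
  expect_equal(nrow(obs0), 25)
  expect_equal(sort(unique(obs0$time)), observation_schedule(238))
  expect_equal(as.numeric(rmse_objective(sim, obs0)), 0, tolerance = 1e-9)
  o1 <- make_observations(sim, seed = 3)
  o2 <- make_observations(sim, seed = 3)
  expect_identical(o1, o2)
  # empirical noise sd close to nominal over many replicates
  set.seed(55)
  reps <- replicate(600, {
    o <- make_observations(sim)
    o$value[o$variable == "k"] - obs0$value[obs0$variable == "k"]
  })
  expect_equal(sd(as.vector(reps)), 0.2, tolerance = 0.05)
  expect_error(make_observations(sim, schedule = c(0, 500)), "span")
})

test_that("fixture cohorts are reproducible on disk and round-trip through
           the fit pipeline inputs", {
  truth <- c(Lp = 10, alpha_LP = 0.05, Jp_max = 5)
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  co1 <- make_fixture_cohort(3, truth, d1, seed = 42)
  co2 <- make_fixture_cohort(3, truth, d2, seed = 42)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # files read back equal the in-memory objects
  p <- read_patient(file.path(d1, "patient-002.json"))
  expect_equal(p$na, co1$patients[[2]]$na)
  o <- read_observations(file.path(d1, "observations-002.csv"))
  expect_equal(o$value, co1$observations[[2]]$value)
  man <- jsonlite::read_json(file.path(d1, "truth-manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$truth$Lp, 10)
  expect_equal(man$n, 3)
  unlink(c(d1, d2), recursive = TRUE)
})
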