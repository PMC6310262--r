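test_that("pump activation is a bounded product of Michaelis factors", {
  fx <- hd_fixed_params()
  expect_equal(pump_activation(0, 10, fx), 0)
  expect_equal(pump_activation(1.5, 10, fx), 0.25)   # both at half-activation
  # cohort-median initial interstitial K and intracellular Na
  expect_equal(pump_activation(0.98 * 5.6, 0.0714 * 140, fx), 0.392595,
               tolerance = 1e-5)
  ck <- seq(0, 12, by = 0.5)
  expect_true(all(diff(pump_activation(ck, 10, fx)) > 0))
  expect_true(all(pump_activation(ck, 10, fx) < 1))
  expect_error(pump_activation(-1, 10, fx), "non-negative")
})

test_that("diffusivity calibration balances pump and diffusion at t = 0", {
  fx <- hd_fixed_params()
  cNa_IS <- 0.98 * 140; cNa_IC <- 0.0714 * 140
  cK_IS <- 0.98 * 5.6; cK_IC <- 35 * 5.6
  w <- calibrate_diffusivities(5.52, cNa_IS, cNa_IC, cK_IS, cK_IC, fx)
  expect_equal(w[["w_Na"]], 51.110, tolerance = 1e-4)
  expect_equal(w[["w_K"]], 22.751, tolerance = 1e-4)
  B0 <- pump_activation(cK_IS, cNa_IC, fx)
  expect_equal(ion_flux("na", cNa_IS, cNa_IC, w[["w_Na"]], B0, 5.52), 0,
               tolerance = 1e-12)
  expect_equal(ion_flux("k", cK_IS, cK_IC, w[["w_K"]], B0, 5.52), 0,
               tolerance = 1e-12)
  expect_equal(calibrate_diffusivities(0, cNa_IS, cNa_IC, cK_IS, cK_IC, fx),
               c(w_Na = 0, w_K = 0))
  expect_error(calibrate_diffusivities(5, 10, 10, cK_IS, cK_IC, fx),
               "undetermined")
})

test_that("a drop in interstitial potassium throttles the pump and lets
           sodium leak into the cells", {
  fx <- hd_fixed_params()
  w_Na <- 51.10977
  B <- pump_activation(3.43, 0.0714 * 140, fx)
  J <- ion_flux("na", 0.98 * 140, 0.0714 * 140, w_Na, B, 5.52)
  # hand evaluation: diffusion 6.5014 in, pump 5.7596 out
  expect_equal(J, 0.74182, tolerance = 1e-4)
  expect_gt(J, 0)
  # without the pump the flux is pure diffusion
  expect_equal(ion_flux("na", 140, 10, 50, 0, 5.52), 0.05 * 130)
})

test_that("doubling the pump rate with recalibration keeps equilibrium but
           doubles both opposing components", {
  fx <- hd_fixed_params()
  cNa_IS <- 0.98 * 140; cNa_IC <- 0.0714 * 140
  cK_IS <- 0.98 * 5.6; cK_IC <- 35 * 5.6
  w1 <- calibrate_diffusivities(5.52, cNa_IS, cNa_IC, cK_IS, cK_IC, fx)
  w2 <- calibrate_diffusivities(11.04, cNa_IS, cNa_IC, cK_IS, cK_IC, fx)
  expect_equal(w2, 2 * w1)
  B0 <- pump_activation(cK_IS, cNa_IC, fx)
  expect_equal(ion_flux("na", cNa_IS, cNa_IC, w2[["w_Na"]], B0, 11.04), 0,
               tolerance = 1e-12)
  # pump and diffusion oppose each other for both ions
  expect_lt(-3 * B0 * 5.52, 0)                        # Na pumped out
  expect_gt(w1[["w_Na"]] / 1000 * (cNa_IS - cNa_IC), 0)  # Na diffuses in
  expect_gt(2 * B0 * 5.52, 0)                         # K pumped in
  expect_lt(w1[["w_K"]] / 1000 * (cK_IS - cK_IC), 0)  # K diffuses out
})

test_that("urea and solute-A fluxes are plain (ratio-shifted) diffusion", {
  expect_equal(urea_flux(50, 50), 0)
  expect_equal(urea_flux(51, 50, 770), 0.77)
  expect_equal(urea_flux(50, 51, 770), -0.77)
  gamma <- (0.98 * 110) / 4.4
  expect_equal(soluteA_flux(0.98 * 110, 4.4, 22.75, gamma), 0)
  expect_equal(soluteA_flux(6, 2, 1000, 1), 4)
  # linear in the offset from equilibrium
  d <- soluteA_flux(0.98 * 110 + 1, 4.4, 500, gamma)
  expect_equal(soluteA_flux(0.98 * 110 + 2, 4.4, 500, gamma), 2 * d)
})

test_that("osmolarity sums described and equivalent osmoles", {
  expect_equal(osmolarity(100, 100, 100, 100, 0, 10, 0.93), 372)
  # the initialization target at the cohort medians
  expect_equal(2 * 140 + 2 * 5.6 + 4.7 + 55.2, 351.1)
  th1 <- osmolarity(140, 5.6, 55.2, 0.5, 1000, 13.1)
  th2 <- osmolarity(140, 5.6, 55.2, 0.5, 2000, 13.1)
  expect_equal(th2 - th1, 0.93 * 1000 / 13.1)
  expect_error(osmolarity(1, 1, 1, 0, 0, -2), "positive")
})

test_that("osmotic water flux follows the transmembrane gradient", {
  expect_equal(water_flux(300, 300), 0)
  expect_equal(water_flux(301, 300, 0.024), 0.024)
  expect_lt(water_flux(300, 305, 0.024), 0)   # hypertonic interstitium
})
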