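test_that("oncotic pressure follows the protein polynomial and is monotone", {
  expect_equal(oncotic_pressure(0), 0)
  expect_equal(oncotic_pressure(6.5), 22.8816, tolerance = 1e-4)
  expect_equal(oncotic_pressure(3.9), 11.1575, tolerance = 1e-4)
  cc <- seq(0, 12, by = 0.25)
  expect_true(all(diff(oncotic_pressure(cc)) > 0))
  expect_error(oncotic_pressure(-1), "non-negative")
})

test_that("reflection coefficient covers the steric limits", {
  # protein is fully reflected by the water-only ultrasmall pores
  expect_equal(reflection_coefficient(35.5, 2), 1)
  expect_equal(reflection_coefficient(35.5, 250), 0.069609, tolerance = 1e-4)
  expect_equal(reflection_coefficient(35.5, 45), 0.912851, tolerance = 1e-4)
  expect_lt(reflection_coefficient(1e-6, 45), 1e-10)   # point solute
  expect_error(reflection_coefficient(-1, 45), "positive")
  expect_error(reflection_coefficient(35.5, 0), "positive")
  # custom rule hook is respected
  expect_equal(reflection_coefficient(10, 100, sigma_fn = function(l) l), 0.1)
})

test_that("pore hydraulics split Lp and order protein permeabilities", {
  fx <- hd_fixed_params()
  po <- pore_hydraulics(11.63, 0.056, fx)
  expect_equal(sum(po$alpha), 1)
  expect_equal(sum(po$Lp_r), 11.63)
  expect_equal(po$sigma[po$pore == "UP"], 1)
  expect_equal(po$PS[po$pore == "UP"], 0)
  # published magnitudes: large-pore PS of order 1 mL/min, exceeding the
  # strongly hindered small-pore pathway
  PS_LP <- po$PS[po$pore == "LP"]
  PS_SP <- po$PS[po$pore == "SP"]
  expect_gt(PS_LP, 0.5)
  expect_lt(PS_LP, 5)
  expect_lt(PS_SP, PS_LP)
  # absent pathway carries nothing
  po0 <- pore_hydraulics(11.63, 0, fx)
  expect_equal(po0$Lp_r[po0$pore == "LP"], 0)
  expect_equal(po0$PS[po0$pore == "LP"], 0)
})

test_that("interstitial pressure is linear in volume with a rigid limit", {
  fx <- hd_fixed_params()
  expect_equal(interstitial_pressure(13.1, 13.1, fx), fx$P_IS0)
  expect_equal(interstitial_pressure(11.6, 13.1, fx), fx$P_IS0 - 1.5)
  rigid <- hd_fixed_params(compliance = 1e12)
  expect_equal(interstitial_pressure(20, 13.1, rigid), rigid$P_IS0,
               tolerance = 1e-9)
  expect_error(interstitial_pressure(-1, 13.1, fx), "positive")
})

test_that("per-pore fluid fluxes sum to the total and scale with Lp", {
  fx <- hd_fixed_params()
  po <- pore_hydraulics(11.63, 0.056, fx)
  set.seed(11)
  for (i in 1:25) {
    P_c <- runif(1, 5, 30); P_IS <- runif(1, -2, 6)
    Pi_P <- runif(1, 10, 30); Pi_IS <- runif(1, 2, 15)
    fl <- capillary_fluid_flux(P_c, P_IS, Pi_P, Pi_IS, po)
    expect_equal(sum(fl$per_pore), fl$total)
  }
  # doubling Lp doubles everything at fixed pressures
  po2 <- pore_hydraulics(2 * 11.63, 0.056, fx)
  f1 <- capillary_fluid_flux(20, 2, 22.9, 11.2, po)
  f2 <- capillary_fluid_flux(20, 2, 22.9, 11.2, po2)
  expect_equal(f2$total, 2 * f1$total)
  # Starling equilibrium: hydraulic gradient equal to the alpha-weighted
  # effective oncotic gradient gives zero net flux
  dPi <- 22.8816 - 11.1575
  dP_eq <- sum(po$alpha * po$sigma) * dPi
  expect_lt(abs(capillary_fluid_flux(2 + dP_eq, 2, 22.8816, 11.1575,
                                     po)$total), 1e-10)
})

test_that("intramembrane mean concentration has the Patlak limits", {
  expect_equal(mean_membrane_concentration(4, 2, 0), 3)
  expect_equal(mean_membrane_concentration(4, 2, 1e-9), 3, tolerance = 1e-8)
  expect_equal(mean_membrane_concentration(4, 2, 1e6), 4, tolerance = 1e-5)
  expect_equal(mean_membrane_concentration(4, 2, -1e6), 2, tolerance = 1e-5)
  expect_equal(mean_membrane_concentration(4, 2, 2), 3.313036,
               tolerance = 1e-5)
  set.seed(21)
  for (i in 1:50) {
    cu <- runif(1, 0, 10); cd <- runif(1, 0, 10); Pe <- runif(1, -50, 50)
    cm <- mean_membrane_concentration(cu, cd, Pe)
    expect_gte(cm, min(cu, cd) - 1e-12)
    expect_lte(cm, max(cu, cd) + 1e-12)
  }
})

test_that("protein flux vanishes at equal concentrations, reduces to pure
           diffusion when fully reflected, and is antisymmetric", {
  fx <- hd_fixed_params()
  po <- pore_hydraulics(11.63, 0.056, fx)
  zero_Jv <- c(LP = 0, SP = 0, UP = 0)
  expect_equal(protein_flux(5, 5, zero_Jv, po), 0)
  # fully reflecting pores: convection sieved out entirely
  po_s1 <- po; po_s1$sigma <- rep(1, 3)
  Jv <- c(LP = 3, SP = 2, UP = 1)
  expect_equal(protein_flux(6, 3, Jv, po_s1),
               sum(po_s1$PS[1:2]) * (6 - 3))
  # exchanging the two sides (and hence reversing the fluid flux)
  # reverses the protein flux exactly
  fl <- capillary_fluid_flux(15, 2, oncotic_pressure(6.5),
                             oncotic_pressure(3.9), po)
  fwd <- protein_flux(65, 39, fl$per_pore, po)
  rev <- protein_flux(39, 65, -fl$per_pore, po)
  expect_equal(rev, -fwd)
})

test_that("lymph flow is linear in interstitial pressure and clamped", {
  fx <- hd_fixed_params()   # LS = 0.4
  at <- function(P) lymph_flow(P, 39, 10, fx)
  expect_equal(at(fx$P_IS0)$Jv_L, 10)
  expect_equal(at(fx$P_IS0 - 1.5)$Jv_L, 4)      # 1 + 0.4 * (-1.5)
  expect_equal(at(fx$P_IS0 - 10)$Jv_L, 0)       # would be negative
  expect_equal(at(fx$P_IS0)$J_TP_L, 390)
})
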