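test_that("water viscosity matches reference values and decreases with T", {
  # independent anchor: tabulated viscosity of water at 20 C is 1.002e-3 Pa s
  expect_equal(water_viscosity(293.15), 1.002e-3, tolerance = 5e-3)
  Tg <- seq(274, 372, by = 1)
  expect_true(all(diff(water_viscosity(Tg)) < 0))
  expect_error(water_viscosity(272), "273")
  expect_error(water_viscosity(373.5), "273")
})

test_that("diffusion fit is exact on noiseless linear input and degrades gracefully", {
  C <- c(0.45, 0.9, 1.35)
  s <- diffusion_series(293, C, 2e-10 * (1 + 0.05 * C))
  fit <- fit_diffusion_series(s)
  expect_equal(fit$D0, 2e-10, tolerance = 1e-12)
  expect_equal(fit$a, 0.05, tolerance = 1e-12)
  expect_lt(fit$residual_norm, 1e-20)

  # single-entry degenerate input
  expect_warning(
    f1 <- fit_diffusion_series(diffusion_series(293, 0.45, 2e-10)),
    "single concentration")
  expect_equal(f1$D0, 2e-10)
  expect_identical(f1$a, 0)
})

test_that("diffusion fit recovers known parameters from noisy data within 3 SE", {
  # Monte-Carlo calibration of the OLS fitter
  C <- c(0.45, 0.9, 1.35)
  D0 <- 1.5e-10; a <- 0.04; sd <- 2e-13
  ests <- withr::with_seed(42, {
    replicate(200, {
      D <- D0 * (1 + a * C) + rnorm(3, 0, sd)
      fit_diffusion_series(diffusion_series(293, C, D))$D0
    })
  })
  se <- sd(ests)
  expect_lt(abs(mean(ests) - D0), 3 * se / sqrt(200))
  expect_lt(abs(ests[1] - D0), 3 * se)
})

test_that("Stokes-Einstein relation inverts and scales correctly", {
  D <- stokes_einstein_d0(24, 283)
  expect_equal(stokes_einstein_rh(D, 283), 24, tolerance = 1e-12)
  expect_equal(stokes_einstein_rh(2 * D, 283),
               12, tolerance = 1e-12)  # doubling D0 halves Rh
  # composition: increasing D0 maps to strictly decreasing Rh at fixed T
  D0s <- seq(1e-10, 3e-10, length.out = 20)
  expect_true(all(diff(stokes_einstein_rh(D0s, 300)) < 0))
})

test_that("Rg/Rh conversion reproduces the disordered-chain anchors and inverts", {
  # printed anchor pairs for a 66-residue chain
  expect_equal(rh_to_rg(17, 66), 12.2, tolerance = 0.05)
  expect_lt(abs(rh_to_rg(24, 66) - 25.44), 0.05)
  # inverse composition identity
  expect_equal(rh_to_rg(rg_to_rh(20, 66), 66), 20, tolerance = 1e-9)
  # monotone over the physical bracket, guaranteeing unique inversion
  Rg <- seq(3, 5 * 66^0.6, length.out = 100)
  expect_true(all(diff(rg_to_rh(Rg, 66)) > 0))
})

test_that("Flory scaling law evaluates and flags unphysical exponents", {
  expect_equal(scaling_rg(66, 2.2, 0.5), 2.2 * sqrt(66))
  expect_equal(scaling_rg(1, 2.2, 0.5), 2.2)
  expect_lt(scaling_rg(66, 2.2, 1 / 3), scaling_rg(66, 2.2, 3 / 5))
  expect_warning(scaling_rg(66, 2.2, 0.7), "physical range")
})

test_that("percent compaction is a relative difference", {
  expect_equal(percent_compaction(17, 15), 100 * 2 / 17)
  expect_equal(percent_compaction(10, 10), 0)
  expect_equal(percent_compaction(20, 10), 50)
})

test_that("the DLS pipeline recovers scenario radii end to end", {
  sc <- collapse_scenario()
  tab <- dls_to_radii(gen_dls_series(sc, a = 0.01), N = 66)
  expect_equal(tab$Rh_A, scenario_rh(sc), tolerance = 1e-9)
  expect_equal(tab$Rh_A[tab$temperature_K == 283], 24, tolerance = 0.01)
  expect_equal(tab$Rh_A[tab$temperature_K == 333], 17, tolerance = 0.02)
  # the lowest-concentration variant is biased up by non-ideality but close
  tab2 <- dls_to_radii(gen_dls_series(sc, a = 0.01), N = 66, use = "lowestC")
  expect_true(all(tab2$Rh_A < tab$Rh_A))
  expect_equal(tab2$Rh_A, tab$Rh_A, tolerance = 0.01)
})
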