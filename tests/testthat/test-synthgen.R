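test_that("scenario construction enforces its physical invariants", {
  expect_error(collapse_scenario(Rh_expanded = c(16, 0)), "exceed")
  expect_error(collapse_scenario(T_c = 400), "inside")
  sc <- collapse_scenario()
  rh <- scenario_rh(sc)
  expect_true(all(diff(rh) < 0))
  expect_equal(rh[1], 24, tolerance = 1e-3)
  expect_equal(rh[length(rh)], 17, tolerance = 0.015)
})

test_that("DLS generator is exact Stokes-Einstein at a = 0 and zero noise", {
  sc <- collapse_scenario()
  series <- gen_dls_series(sc, concentrations = 0.9, a = 0)
  D_expected <- stokes_einstein_d0(scenario_rh(sc), sc$T_grid)
  expect_equal(vapply(series, function(s) s$D, numeric(1)), D_expected)
  expect_error(gen_dls_series(sc, concentrations = c(-1, 1)), "positive")
})

test_that("generators are bitwise-reproducible under a fixed seed", {
  sc <- collapse_scenario()
  n <- noise_spec(sd = 1e-12, seed = 101)
  expect_identical(gen_dls_series(sc, noise = n),
                   gen_dls_series(sc, noise = n))
  vb <- vb_params(1554.9, -173.7, 291.7, 0.535)
  nn <- noise_spec(sd = 1e-6, seed = 5)
  expect_identical(gen_thermograms(vb, noise = nn),
                   gen_thermograms(vb, noise = nn))
  m <- heterogeneity_model(-26, 4, 298)
  nr <- noise_spec(sd = 0.002, seed = 17)
  expect_identical(gen_binding_isotherms(m, noise = nr),
                   gen_binding_isotherms(m, noise = nr))
  # different seeds differ
  expect_false(identical(
    gen_binding_isotherms(m, noise = noise_spec(0.002, 17)),
    gen_binding_isotherms(m, noise = noise_spec(0.002, 18))))
})

test_that("generated excess Cp is single-peaked and the DSC span matches the study range", {
  vb <- vb_params(1554.9, -173.7, 291.7, 0.535)
  th <- gen_thermograms(vb, concentrations = c(52, 110))
  expect_equal(vapply(th, function(x) x$concentration_uM, numeric(1)),
               c(52, 110))
  curve <- absolute_cp(th, molar_mass = 7500)
  ce <- curve$cp_excess
  expect_true(all(diff(sign(diff(ce))) <= 0))
  expect_warning(gen_thermograms(vb, concentrations = 52), ">= 2")
})

test_that("binding generator maps the ensemble through the anisotropy observable", {
  m <- heterogeneity_model(8.314e-3 * 308 * log(9e-6), 4.5, 308)
  iso <- gen_binding_isotherms(m)
  expect_equal(iso$signal,
               0.06 + 0.1 * ensemble_isotherm(m, iso$conc))
  fit <- hill_fit(iso)
  expect_equal(fit$n_H, 0.69, tolerance = 0.05)
  expect_error(gen_binding_isotherms(m, r_free = 0.2, r_bound = 0.1),
               "exceed")
  # homogeneous limit: Hill fit of noiseless output returns n_H = 1
  m0 <- heterogeneity_model(8.314e-3 * 298 * log(1e-5), 0, 298)
  expect_equal(hill_fit(gen_binding_isotherms(m0))$n_H, 1,
               tolerance = 1e-5)
})

test_that("melt and spectral generators reject empty grids", {
  expect_error(gen_melt_curve(307, 200, T_grid = numeric(0)), "empty")
  expect_error(gen_spectral_matrix(T_grid = numeric(0)), "empty")
})

test_that("estimator noise scales as expected with the noise level", {
  # standard error of the fitted midpoint roughly doubles with noise sd
  Tg <- seq(278, 350, by = 2)
  tm_at <- function(sdn) vapply(1:40, function(seed)
    two_state_fit(gen_melt_curve(307, 200, T_grid = Tg,
                                 noise = noise_spec(sdn, seed)))$T_m,
    numeric(1))
  s1 <- sd(tm_at(0.005))
  s2 <- sd(tm_at(0.02))
  expect_gt(s2 / s1, 2)
  expect_lt(s2 / s1, 8)
})
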