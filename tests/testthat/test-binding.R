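R_kJ <- 8.314e-3

test_that("single-site fraction has the right midpoint and limits", {
  expect_equal(single_site_fraction(1e-5, 1e-5), 0.5)
  expect_lt(single_site_fraction(1e-12, 1e-5), 1e-6)
  expect_gt(single_site_fraction(10, 1e-5), 1 - 1e-5)
  # Hill fit of a single-site curve returns n_H = 1
  g <- default_titration_grid()
  iso <- binding_isotherm(298, g, single_site_fraction(g, 1e-5),
                          kind = "fraction")
  expect_equal(hill_fit(iso)$n_H, 1, tolerance = 1e-6)
})

test_that("ensemble isotherm degenerates to single-site at sigma = 0 and is midpoint-symmetric", {
  g <- default_titration_grid()
  m0 <- heterogeneity_model(R_kJ * 298 * log(1e-5), 0, 298)
  expect_equal(ensemble_isotherm(m0, g), single_site_fraction(g, 1e-5))
  # bulk fraction at L = median Kd is exactly 1/2 (log-symmetry)
  m <- heterogeneity_model(R_kJ * 278 * log(23e-6), 5.1, 278)
  expect_equal(ensemble_isotherm(m, sort(c(g, median_kd(m))))[
    which(sort(c(g, median_kd(m))) == median_kd(m))], 0.5, tolerance = 1e-9)
})

test_that("Monte-Carlo and quadrature ensemble isotherms agree within sampling error", {
  g <- default_titration_grid()
  mq <- heterogeneity_model(R_kJ * 278 * log(23e-6), 5.1, 278)
  fq <- ensemble_isotherm(mq, g)
  for (seed in 1:3) {
    mmc <- heterogeneity_model(R_kJ * 278 * log(23e-6), 5.1, 278,
                               n_molecules = 1000, mode = "monte-carlo",
                               seed = seed)
    fmc <- ensemble_isotherm(mmc, g)
    # per-point sampling SE of a mean of 1000 bounded fractions
    se <- sqrt(fq * (1 - fq) / 1000) + 1e-4
    expect_true(all(abs(fmc - fq) < 3.5 * se))
  }
  # seeded determinism
  m1 <- heterogeneity_model(-26, 5, 298, mode = "monte-carlo", seed = 9)
  expect_identical(ensemble_isotherm(m1, g), ensemble_isotherm(m1, g))
})

test_that("heterogeneity widths from the binding study map onto sub-unity Hill coefficients", {
  g <- default_titration_grid()
  cases <- list(list(sigma = 5.1, T = 278, K = 23e-6, nH = 0.60),
                list(sigma = 4.5, T = 308, K = 9e-6, nH = 0.69))
  for (cs in cases) {
    m <- heterogeneity_model(R_kJ * cs$T * log(cs$K), cs$sigma, cs$T)
    fit <- hill_fit(binding_isotherm(cs$T, g, ensemble_isotherm(m, g),
                                     kind = "fraction"))
    expect_equal(fit$n_H, cs$nH, tolerance = 0.05)
    # fitted midpoint tracks the median Kd within 2% (log-symmetry)
    expect_equal(fit$K_half, median_kd(m), tolerance = 0.02)
  }
})

test_that("hill_fit recovers exact Hill curves and rejects flat signals", {
  g <- default_titration_grid()
  f <- g^1 / (10e-6^1 + g^1)
  fit <- hill_fit(binding_isotherm(298, g, f, kind = "fraction"))
  expect_equal(fit$n_H, 1, tolerance = 1e-8)
  expect_equal(fit$K_half, 10e-6, tolerance = 1e-8)
  # joint amplitude estimation on exact anisotropy data
  r <- anisotropy_from_fraction(f, 0.06, 0.16)
  fa <- hill_fit(binding_isotherm(298, g, r, kind = "anisotropy"))
  expect_equal(fa$n_H, 1, tolerance = 1e-6)
  expect_equal(fa$K_half, 10e-6, tolerance = 1e-6)
  expect_equal(fa$r_free, 0.06, tolerance = 1e-6)
  expect_equal(fa$r_bound, 0.16, tolerance = 1e-6)
  expect_error(
    hill_fit(binding_isotherm(298, g, rep(0.06, length(g)),
                              kind = "anisotropy")),
    "no binding")
})

test_that("anisotropy mapping is linear with the stated endpoints", {
  expect_equal(anisotropy_from_fraction(0, 0.06, 0.16), 0.06)
  expect_equal(anisotropy_from_fraction(1, 0.06, 0.16), 0.16)
  expect_equal(anisotropy_from_fraction(0.5, 0.06, 0.16),
               mean(c(0.06, 0.16)))
  expect_error(anisotropy_from_fraction(0.5, 0.16, 0.06), "exceed")
  expect_error(anisotropy_from_fraction(1.5, 0.06, 0.16), "\\[0, 1\\]")
})

test_that("the midpoint-slope oracle matches the fitted Hill coefficient", {
  m <- heterogeneity_model(R_kJ * 278 * log(23e-6), 5.1, 278)
  nh_mid <- midpoint_slope_nh(m)
  expect_equal(nh_mid, 0.57, tolerance = 0.01)
  g <- default_titration_grid()
  fit <- hill_fit(binding_isotherm(278, g, ensemble_isotherm(m, g),
                                   kind = "fraction"))
  expect_lt(abs(nh_mid - fit$n_H), 0.05)
  expect_equal(midpoint_slope_nh(heterogeneity_model(-25, 0, 298)), 1)
})

test_that("n_H decreases strictly with sigma and is invariant to mu", {
  g <- default_titration_grid()
  nh <- vapply(seq(0, 8, by = 1), function(s) {
    m <- heterogeneity_model(R_kJ * 298 * log(1e-5), s, 298)
    hill_fit(binding_isotherm(298, g, ensemble_isotherm(m, g),
                              kind = "fraction"))$n_H
  }, numeric(1))
  expect_equal(nh[1], 1, tolerance = 1e-4)
  expect_true(all(diff(nh) < 0))
  # shift invariance in log concentration
  nh_shift <- vapply(c(2e-5, 5e-6), function(K) {
    m <- heterogeneity_model(R_kJ * 298 * log(K), 4, 298)
    hill_fit(binding_isotherm(298, g, ensemble_isotherm(m, g),
                              kind = "fraction"))$n_H
  }, numeric(1))
  expect_lt(abs(diff(nh_shift)), 1e-3)
})

test_that("sigma inference inverts the forward Hill map", {
  g <- default_titration_grid()
  # identity on sigma for the widths relevant to the binding study
  for (s in c(2, 3, 4.5, 5.1)) {
    m <- heterogeneity_model(R_kJ * 298 * log(1e-5), s, 298)
    fit <- hill_fit(binding_isotherm(298, g, ensemble_isotherm(m, g),
                                     kind = "fraction"))
    inf <- infer_sigma(fit$n_H, fit$K_half, 298)
    expect_lt(abs(inf$sigma - s), 0.1)
  }
  # homogeneous limit and error contracts
  inf1 <- infer_sigma(1, 1e-5, 298)
  expect_lt(inf1$sigma, 0.05)
  expect_error(infer_sigma(1.2, 1e-5, 298), "n_H")
  expect_error(infer_sigma(0.2, 1e-5, 298, sigma_max = 3), "bracket")
})
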