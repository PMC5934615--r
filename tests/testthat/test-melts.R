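test_that("two-state fit recovers generating parameters exactly at zero noise", {
  cv <- gen_melt_curve(307, 220, probe = "near_uv_cd")
  fit <- two_state_fit(cv)
  expect_equal(fit$T_m, 307, tolerance = 1e-6)
  expect_equal(fit$dH_vH, 220, tolerance = 1e-5)
  expect_equal(fit$baseline_expanded, c(1, -0.002), tolerance = 1e-4)
  # populations are a proper two-state pair, P(T_m) = 1/2
  expect_true(all(fit$P_UE >= 0 & fit$P_UE <= 1))
  expect_true(all(diff(fit$P_UE) < 0))     # decreasing in T for dH > 0
  mid <- approx(cv$T, fit$P_UE, xout = fit$T_m)$y
  expect_equal(mid, 0.5, tolerance = 1e-3)  # linear interpolation on the grid
  expect_equal(fit$P_UE + (1 - fit$P_UE), rep(1, length(fit$P_UE)))
})

test_that("monotone featureless signals are rejected as transition-free", {
  Tg <- seq(278, 350, by = 2)
  expect_error(two_state_fit(probe_curve(Tg, 2 - 0.001 * Tg, "flat")),
               "no transition")
})

test_that("two-state midpoint recovery holds to 1 K at SNR 20 over 100 replicates", {
  # cooperative melt (dH = 250 kJ/mol) sampled every 0.5 K, as from a
  # continuous-ramp CD measurement; noise set to 1/20 of the transition
  # amplitude at the midpoint
  Tg <- seq(278, 350, by = 0.5)
  amp <- abs((1 - 0.002 * 307) - (0.1 - 0.0005 * 307))
  sdn <- amp / 20
  errs <- vapply(1:100, function(seed) {
    cv <- gen_melt_curve(307, 250, T_grid = Tg,
                         noise = noise_spec(sdn, seed))
    fit <- two_state_fit(cv)
    c(fit$T_m - 307, fit$dH_vH / 250 - 1)
  }, numeric(2))
  expect_lt(max(abs(errs[1, ])), 1)             # T_m within 1 K, every replicate
  expect_lt(sqrt(mean(errs[2, ]^2)), 0.10)      # dH_vH within 10% as RMS error
})

test_that("collapse summary orders probes and reports the midpoint spread", {
  probes <- default_melt_probes()
  fits <- lapply(seq_len(nrow(probes)), function(i)
    two_state_fit(gen_melt_curve(probes$T_m_K[i], probes$dH_kJmol[i],
                                 probe = probes$probe[i])))
  tab <- collapse_summary(fits)
  expect_equal(tab$probe,
               c("fluorescence_shift", "near_uv_cd", "dls_rh"))
  expect_equal(attr(tab, "spread_K"), 11, tolerance = 1e-4)
  expect_equal(attr(collapse_summary(fits[2]), "spread_K"), 0)
  # identical probes give identical rows
  tab2 <- collapse_summary(fits[c(2, 2)])
  expect_equal(tab2$T_m_K[1], tab2$T_m_K[2])
})

test_that("SVD of spectral matrices conserves energy and resolves the shift mode", {
  m2 <- gen_spectral_matrix()
  s <- svd_spectra(m2)
  # construction is rank 2: third singular value vanishes
  expect_lt(s$d[3], 1e-10 * s$d[1])
  expect_lt(s$residual_fronorm, 1e-10)
  # energy conservation
  expect_equal(sum(s$d^2), sum(m2$M^2), tolerance = 1e-10)
  # non-increasing singular values, sign convention on basis spectra
  expect_true(all(diff(s$d) <= 1e-12))
  expect_true(all(colMeans(s$U) >= 0))
  # the second amplitude changes sign across the shift midpoint
  expect_equal(sum(diff(sign(s$V[, 2])) != 0), 1)
  flip <- s$T[which(diff(sign(s$V[, 2])) != 0)]
  expect_lt(abs(flip - 301), 3)
  # rank-1 input: second singular value vanishes
  m1 <- gen_spectral_matrix(shift_amplitude = 0)
  expect_lt(svd_spectra(m1)$d[2], 1e-10 * svd_spectra(m1)$d[1])
})

test_that("spectral matrices refuse missing cells", {
  M <- matrix(1, 3, 3)
  M[2, 2] <- NA
  expect_error(spectral_matrix(1:3, 1:3, M), "missing")
})
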