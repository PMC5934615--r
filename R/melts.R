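# Two-state analysis of single-probe melting curves and SVD of spectral
# matrices. The two states are the expanded coil (U_E, low temperature) and
# the collapsed globule (U_C, high temperature); each probe reports its own
# apparent midpoint, and the spread of midpoints across probes measures the
# degree of energetic decoupling of the transition.

#' Probe signal curve
#'
#' @param T strictly increasing temperature grid in K (>= 8 points).
#' @param signal probe signal on the grid (any units).
#' @param probe character label for the probe.
#' @return an object of class `probe_curve`.
#' @export
probe_curve <- function(T, signal, probe = "probe") {
  stopifnot(length(T) == length(signal))
  if (length(T) < 8L) {
    stop("probe_curve: need >= 8 temperature points", call. = FALSE)
  }
  if (any(diff(T) <= 0)) {
    stop("probe_curve: temperature grid must be strictly increasing",
         call. = FALSE)
  }
  structure(list(T = as.numeric(T), signal = as.numeric(signal),
                 probe = probe),
            class = "probe_curve")
}

#' @export
print.probe_curve <- function(x, ...) {
  cat(sprintf("<probe_curve> '%s', %d points over %.1f-%.1f K\n",
              x$probe, length(x$T), min(x$T), max(x$T)))
  invisible(x)
}

two_state_pop <- function(T, T_m, dH, dCp = 0) {
  R <- idp_constants$R
  dG <- dH * (1 - T / T_m) +
    if (dCp != 0) dCp * (T - T_m - T * log(T / T_m)) else 0
  K <- exp(-dG / (R * T))    # [U_C]/[U_E]
  1 / (1 + K)                # P(U_E)
}

two_state_signal <- function(T, T_m, dH, bE, bC, dCp = 0) {
  p <- two_state_pop(T, T_m, dH, dCp)
  sE <- bE[1] + bE[2] * T
  sC <- bC[1] + bC[2] * T
  p * sE + (1 - p) * sC
}

#' Two-state fit of a melting curve
#'
#' Fits \eqn{S(T) = P_E S_E(T) + (1 - P_E) S_C(T)} with linear baselines for
#' both states and van't Hoff populations
#' \eqn{P_E = 1/(1 + e^{-\Delta G/RT})},
#' \eqn{\Delta G(T) = \Delta H_{vH} (1 - T/T_m)} (an optional fixed
#' \eqn{\Delta C_p} adds the standard curvature term, default 0).
#'
#' @param curve a [probe_curve()].
#' @param dCp fixed heat-capacity change of the transition in
#'   kJ mol^-1 K^-1 (default 0, van't Hoff form).
#' @return an object of class `two_state_fit`: list with `T_m` (K), `dH_vH`
#'   (kJ mol^-1), `baseline_expanded` and `baseline_collapsed` (intercept,
#'   slope), `P_UE` (population of the expanded state on the data grid),
#'   `probe`, `residual_norm`.
#' @export
two_state_fit <- function(curve, dCp = 0) {
  stopifnot(inherits(curve, "probe_curve"))
  T <- curve$T
  y <- curve$signal
  n <- length(T)
  k <- max(3L, floor(n / 4))
  bE0 <- stats::coef(stats::lm(y[1:k] ~ T[1:k]))
  bC0 <- stats::coef(stats::lm(y[(n - k + 1):n] ~ T[(n - k + 1):n]))
  # crude midpoint: where the baseline-corrected signal crosses 1/2
  mid_resid <- abs((y - (bC0[1] + bC0[2] * T)) /
                     ((bE0[1] + bE0[2] * T) - (bC0[1] + bC0[2] * T)) - 0.5)
  Tm0 <- T[which.min(mid_resid)]
  if (Tm0 <= min(T) || Tm0 >= max(T)) Tm0 <- stats::median(T)
  fit <- try(minpack.lm::nlsLM(
    y ~ two_state_signal(T, Tm, dH, c(aE, bE), c(aC, bC), dCp),
    start = list(Tm = Tm0, dH = 200, aE = unname(bE0[1]), bE = unname(bE0[2]),
                 aC = unname(bC0[1]), bC = unname(bC0[2])),
    lower = c(min(T) - 20, 1, -Inf, -Inf, -Inf, -Inf),
    upper = c(max(T) + 20, 5000, Inf, Inf, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("two_state_fit: no transition detectable in '", curve$probe, "'",
         call. = FALSE)
  }
  co <- stats::coef(fit)
  rn <- sqrt(sum(stats::resid(fit)^2))
  # a transition must actually modulate the signal beyond the residual scale
  amp <- abs((co["aE"] + co["bE"] * co["Tm"]) - (co["aC"] + co["bC"] * co["Tm"]))
  if (!is.finite(amp) || amp < 3 * rn / sqrt(length(T))) {
    stop("two_state_fit: no transition detectable in '", curve$probe, "'",
         call. = FALSE)
  }
  structure(
    list(T_m = unname(co["Tm"]), dH_vH = unname(co["dH"]),
         baseline_expanded = unname(co[c("aE", "bE")]),
         baseline_collapsed = unname(co[c("aC", "bC")]),
         T = T, P_UE = two_state_pop(T, co["Tm"], co["dH"], dCp),
         probe = curve$probe, residual_norm = rn, dCp = dCp),
    class = "two_state_fit"
  )
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("<two_state_fit> '%s': T_m = %.2f K, dH_vH = %.1f kJ/mol\n",
              x$probe, x$T_m, x$dH_vH))
  invisible(x)
}

#' Summarize apparent midpoints across probes
#'
#' Orders the probes by apparent midpoint and reports the max-min spread, a
#' simple statistic of how energetically decoupled the structural
#' transitions monitored by the different probes are (0 for a fully coupled
#' two-state system).
#'
#' @param fits a list of [two_state_fit()] objects (>= 1).
#' @return a data.frame with columns `probe`, `T_m_K`, `dH_vH_kJmol`,
#'   carrying the midpoint spread in K as attribute `"spread_K"`.
#' @export
collapse_summary <- function(fits) {
  stopifnot(length(fits) >= 1L)
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(probe = f$probe, T_m_K = f$T_m, dH_vH_kJmol = f$dH_vH)))
  tab <- tab[order(tab$T_m_K), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "spread_K") <- max(tab$T_m_K) - min(tab$T_m_K)
  tab
}

#' Spectral matrix container
#'
#' Wavelength-by-temperature matrix of emission (or ellipticity) spectra.
#'
#' @param wavelength wavelengths in nm (rows).
#' @param T temperatures in K (columns).
#' @param M numeric matrix, `length(wavelength)` x `length(T)`, no missing
#'   cells.
#' @return an object of class `spectral_matrix`.
#' @export
spectral_matrix <- function(wavelength, T, M) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == length(wavelength), ncol(M) == length(T))
  if (anyNA(M)) {
    stop("spectral_matrix: missing cells are not allowed", call. = FALSE)
  }
  structure(list(wavelength = as.numeric(wavelength), T = as.numeric(T),
                 M = M),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d wavelengths x %d temperatures\n",
              nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Singular value decomposition of a spectral matrix
#'
#' Uncentered SVD (the first component then reports on the average
#' spectrum). Each retained basis spectrum is sign-oriented so that its mean
#' is non-negative, with the matching amplitude vector flipped accordingly.
#'
#' @param mat a [spectral_matrix()].
#' @param n_components number of components to retain (default 2).
#' @return an object of class `svd_spectra`: list with `wavelength`, `T`,
#'   `d` (all singular values, non-increasing), `U` (retained basis
#'   spectra, columns), `V` (retained temperature amplitudes, columns;
#'   scaled by the singular values so `U %*% t(V)` reconstructs the
#'   retained part), and `residual_fronorm`.
#' @export
svd_spectra <- function(mat, n_components = 2L) {
  stopifnot(inherits(mat, "spectral_matrix"), n_components >= 1L)
  s <- svd(mat$M)
  k <- min(n_components, length(s$d))
  U <- s$u[, 1:k, drop = FALSE]
  V <- s$v[, 1:k, drop = FALSE] %*% diag(s$d[1:k], k, k)
  for (j in 1:k) {
    if (mean(U[, j]) < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  recon <- U %*% t(V)
  structure(
    list(wavelength = mat$wavelength, T = mat$T, d = s$d,
         U = U, V = V,
         residual_fronorm = sqrt(sum((mat$M - recon)^2))),
    class = "svd_spectra"
  )
}

#' @export
print.svd_spectra <- function(x, ...) {
  cat(sprintf("<svd_spectra> %d component(s) retained; singular values: %s\n",
              ncol(x$U),
              paste(signif(utils::head(x$d, 4), 4), collapse = ", ")))
  invisible(x)
}
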