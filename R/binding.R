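# Hill analysis and the quenched-heterogeneity ensemble model of binding.
#
# Each molecule binds its ligand 1:1 with a fixed (quenched) standard
# binding free energy dG drawn from Normal(mu, sigma^2); Kd = exp(dG/(RT))
# relative to a 1 M reference state. Averaging the per-molecule isotherms
# gives a bulk isotherm that is shallower than 1:1 whenever sigma > 0 and
# fits the Hill equation with n_H < 1: apparent negative cooperativity from
# molecular heterogeneity, not from multi-site binding.

#' Fraction bound for 1:1 binding
#'
#' \eqn{f = L / (L + K_d)}.
#'
#' @param L free ligand (titrant) concentration in M (> 0).
#' @param Kd dissociation constant in M (> 0).
#' @return fraction bound in \[0, 1\].
#' @export
single_site_fraction <- function(L, Kd) {
  stopifnot(all(L > 0), all(Kd > 0))
  L / (L + Kd)
}

#' Quenched-heterogeneity binding model
#'
#' Gaussian distribution of per-molecule standard binding free energies.
#'
#' @param mu_dG mean standard binding free energy in kJ mol^-1 (1 M
#'   reference; negative for favourable binding).
#' @param sigma standard deviation of the distribution in kJ mol^-1 (>= 0).
#' @param T temperature in K.
#' @param n_molecules ensemble size for Monte-Carlo averaging (default
#'   1000).
#' @param mode `"quadrature"` (deterministic Gauss-Hermite expectation,
#'   default) or `"monte-carlo"` (explicit n-molecule ensemble).
#' @param seed integer seed for the Monte-Carlo draw.
#' @return an object of class `heterogeneity_model`.
#' @export
heterogeneity_model <- function(mu_dG, sigma, T, n_molecules = 1000L,
                                mode = c("quadrature", "monte-carlo"),
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(sigma >= 0, n_molecules >= 1L, T > 0)
  structure(
    list(mu_dG = mu_dG, sigma = sigma, T = T,
         n_molecules = as.integer(n_molecules), mode = mode,
         seed = as.integer(seed)),
    class = "heterogeneity_model"
  )
}

#' @export
print.heterogeneity_model <- function(x, ...) {
  cat(sprintf(
    "<heterogeneity_model> mu = %.2f kJ/mol, sigma = %.2f kJ/mol, T = %.1f K (%s, n = %d)\n",
    x$mu_dG, x$sigma, x$T, x$mode, x$n_molecules))
  cat(sprintf("  median Kd = %.3g M\n", median_kd(x)))
  invisible(x)
}

#' Median dissociation constant of a heterogeneity model
#'
#' The Gaussian in dG maps to a log-normal in Kd, whose median is
#' \eqn{\exp(\mu/(RT))} (1 M reference).
#'
#' @param model a [heterogeneity_model()].
#' @return median Kd in M.
#' @export
median_kd <- function(model) {
  exp(model$mu_dG / (idp_constants$R * model$T))
}

gauss_hermite_nodes <- function(n = 64L) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

#' Bulk binding isotherm of a heterogeneous ensemble
#'
#' Averages per-molecule 1:1 isotherms over the Gaussian free-energy
#' distribution. In quadrature mode the expectation is taken by
#' Gauss-Hermite quadrature (deterministic); in Monte-Carlo mode
#' `n_molecules` free energies are drawn (seeded) and the sampled isotherms
#' averaged. With `sigma = 0` both modes reduce exactly to the single-site
#' curve. The free-ligand approximation is used: the titrant concentration
#' is taken as the free concentration, appropriate when the midpoint is far
#' above the reporter concentration.
#'
#' @param model a [heterogeneity_model()].
#' @param grid strictly increasing, positive titrant concentrations in M.
#' @return numeric vector of bulk fraction bound on `grid`.
#' @export
ensemble_isotherm <- function(model, grid) {
  stopifnot(inherits(model, "heterogeneity_model"))
  check_conc_grid(grid)
  R <- idp_constants$R
  if (model$sigma == 0) {
    return(single_site_fraction(grid, median_kd(model)))
  }
  if (model$mode == "quadrature") {
    gh <- gauss_hermite_nodes()
    dG <- model$mu_dG + sqrt(2) * model$sigma * gh$x
    Kd <- exp(dG / (R * model$T))
    vapply(grid, function(l) sum(gh$w * l / (l + Kd)), numeric(1))
  } else {
    dG <- withr::with_seed(model$seed,
                           stats::rnorm(model$n_molecules, model$mu_dG,
                                        model$sigma))
    Kd <- exp(dG / (R * model$T))
    vapply(grid, function(l) mean(l / (l + Kd)), numeric(1))
  }
}

check_conc_grid <- function(grid) {
  if (length(grid) < 2L || any(grid <= 0) || any(diff(grid) <= 0)) {
    stop("concentration grid must be strictly increasing and positive",
         call. = FALSE)
  }
  invisible(grid)
}

#' Default titration grid
#'
#' 24 log-spaced concentrations over 1 nM to 100 uM, the span of a typical
#' anisotropy titration. The fitted Hill coefficient depends (weakly) on the
#' grid, so the grid is part of a fit's provenance.
#'
#' @param n number of points.
#' @param lo,hi grid limits in M.
#' @return numeric vector of concentrations in M.
#' @export
default_titration_grid <- function(n = 24L, lo = 1e-9, hi = 1e-4) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

#' Binding isotherm container
#'
#' @param T temperature in K.
#' @param conc strictly increasing, positive titrant concentrations in M
#'   (>= 6 points for fitting).
#' @param signal measured signal on `conc`: anisotropy or fraction bound.
#' @param kind `"anisotropy"` or `"fraction"`.
#' @return an object of class `binding_isotherm`.
#' @export
binding_isotherm <- function(T, conc, signal,
                             kind = c("anisotropy", "fraction")) {
  kind <- match.arg(kind)
  check_conc_grid(conc)
  stopifnot(length(conc) == length(signal), length(conc) >= 6L, T > 0)
  structure(
    list(T = T, conc = as.numeric(conc), signal = as.numeric(signal),
         kind = kind),
    class = "binding_isotherm"
  )
}

#' @export
print.binding_isotherm <- function(x, ...) {
  cat(sprintf("<binding_isotherm> T = %.1f K, %d points (%.3g-%.3g M), kind = %s\n",
              x$T, length(x$conc), min(x$conc), max(x$conc), x$kind))
  invisible(x)
}

#' Convert fraction bound to anisotropy
#'
#' Linear spectroscopic mapping \eqn{r = r_{free} + (r_{bound} - r_{free}) f}.
#'
#' @param f fraction bound in \[0, 1\].
#' @param r_free anisotropy of the free reporter.
#' @param r_bound anisotropy of the bound reporter; must exceed `r_free`.
#' @return anisotropy values.
#' @export
anisotropy_from_fraction <- function(f, r_free, r_bound) {
  if (r_bound <= r_free) {
    stop("anisotropy_from_fraction: r_bound must exceed r_free", call. = FALSE)
  }
  if (any(f < -1e-12 | f > 1 + 1e-12)) {
    stop("anisotropy_from_fraction: fraction bound outside [0, 1]", call. = FALSE)
  }
  r_free + (r_bound - r_free) * f
}

#' Fit the Hill equation to a binding isotherm
#'
#' Least-squares fit of
#' \eqn{f = L^{n_H} / (K_{1/2}^{n_H} + L^{n_H})} by Levenberg-Marquardt.
#' For anisotropy data the amplitudes `r_free` and `r_bound` are fitted
#' jointly; for fraction-bound data they are fixed at 0 and 1. A flat
#' signal (range below three times the noise level estimated from
#' second differences) raises an error.
#'
#' @param isotherm a [binding_isotherm()].
#' @return an object of class `hill_fit`: list with `K_half` (M), `n_H`,
#'   `r_free`, `r_bound`, `se` (named standard errors), `residual_norm`,
#'   `T`, `kind`.
#' @export
hill_fit <- function(isotherm) {
  stopifnot(inherits(isotherm, "binding_isotherm"))
  L <- isotherm$conc
  y <- isotherm$signal
  noise_sd <- stats::sd(diff(diff(y))) / sqrt(6)
  if (!is.finite(noise_sd)) noise_sd <- 0
  if (diff(range(y)) < 3 * noise_sd || diff(range(y)) == 0) {
    stop("hill_fit: no binding detected (signal range below noise)",
         call. = FALSE)
  }
  K0 <- L[which.min(abs((y - min(y)) / diff(range(y)) - 0.5))]
  if (isotherm$kind == "fraction") {
    fit <- minpack.lm::nlsLM(
      y ~ L^n / (K^n + L^n),
      start = list(n = 1, K = K0),
      lower = c(1e-3, min(L) * 1e-3), upper = c(10, max(L) * 1e3),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- stats::coef(fit)
    rf <- 0; rb <- 1
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ rf + (rb - rf) * L^n / (K^n + L^n),
      start = list(n = 1, K = K0, rf = min(y), rb = max(y)),
      lower = c(1e-3, min(L) * 1e-3, -Inf, -Inf),
      upper = c(10, max(L) * 1e3, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    co <- stats::coef(fit)
    rf <- unname(co["rf"]); rb <- unname(co["rb"])
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  structure(
    list(K_half = unname(co["K"]), n_H = unname(co["n"]),
         r_free = rf, r_bound = rb,
         se = se, residual_norm = sqrt(sum(stats::resid(fit)^2)),
         T = isotherm$T, kind = isotherm$kind),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> T = %.1f K: K_1/2 = %.3g M, n_H = %.3f\n",
              x$T, x$K_half, x$n_H))
  if (x$kind == "anisotropy") {
    cat(sprintf("  amplitudes: r_free = %.4f, r_bound = %.4f\n",
                x$r_free, x$r_bound))
  }
  invisible(x)
}

#' Midpoint-slope Hill coefficient of a heterogeneity model
#'
#' Analytic-style oracle for the fitted Hill coefficient: the logit slope of
#' the bulk isotherm at its midpoint, \eqn{n_H = 4 E[f (1 - f)]} evaluated
#' at L = median Kd by Gauss-Hermite quadrature. Equals 1 exactly at
#' sigma = 0 and decreases monotonically with sigma.
#'
#' @param model a [heterogeneity_model()].
#' @return midpoint Hill coefficient (dimensionless).
#' @export
midpoint_slope_nh <- function(model) {
  stopifnot(inherits(model, "heterogeneity_model"))
  if (model$sigma == 0) return(1)
  gh <- gauss_hermite_nodes()
  R <- idp_constants$R
  dG <- model$mu_dG + sqrt(2) * model$sigma * gh$x
  Kd <- exp(dG / (R * model$T))
  Lmid <- median_kd(model)
  f <- Lmid / (Lmid + Kd)
  4 * sum(gh$w * f * (1 - f))
}

#' Infer the binding-free-energy width from an observed Hill coefficient
#'
#' Inverts the monotone map sigma -> fitted n_H: bisection on
#' sigma in \[0, 12\] kJ mol^-1 (tolerance 0.01 kJ mol^-1) using the
#' deterministic quadrature ensemble plus [hill_fit()], then sets the mean
#' mu so the fitted bulk midpoint matches the target K_1/2 (the Hill
#' coefficient is invariant to mu, which only shifts the isotherm in log
#' concentration).
#'
#' @param target_nH observed Hill coefficient, in (0, 1].
#' @param target_Khalf observed midpoint in M.
#' @param T temperature in K.
#' @param grid titrant grid in M (default [default_titration_grid()]).
#' @param sigma_max upper bracket for sigma in kJ mol^-1.
#' @param tol bisection tolerance in kJ mol^-1.
#' @return an object of class `sigma_inference`: list with `model` (the
#'   inferred [heterogeneity_model()]), `sigma`, `mu_dG`, `achieved_nH`,
#'   `achieved_Khalf`, `grid`.
#' @export
infer_sigma <- function(target_nH, target_Khalf, T,
                        grid = default_titration_grid(),
                        sigma_max = 12, tol = 0.01) {
  stopifnot(target_nH > 0, target_Khalf > 0, T > 0)
  if (target_nH > 1 + 1e-6) {
    stop("infer_sigma: target n_H > 1 cannot arise from quenched heterogeneity",
         call. = FALSE)
  }
  check_conc_grid(grid)
  R <- idp_constants$R
  mu0 <- R * T * log(target_Khalf)
  fit_nh <- function(sigma) {
    m <- heterogeneity_model(mu0, sigma, T)
    iso <- binding_isotherm(T, grid, ensemble_isotherm(m, grid),
                            kind = "fraction")
    hill_fit(iso)$n_H
  }
  if (fit_nh(0) < target_nH - 0.02) {
    stop("infer_sigma: target n_H exceeds the homogeneous (sigma = 0) value",
         call. = FALSE)
  }
  if (fit_nh(sigma_max) > target_nH) {
    stop(sprintf(
      "infer_sigma: no bracket; n_H at sigma = %g still above target", sigma_max),
      call. = FALSE)
  }
  lo <- 0; hi <- sigma_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fit_nh(mid) > target_nH) lo <- mid else hi <- mid
  }
  sigma <- (lo + hi) / 2
  # match the midpoint: shift mu so the fitted K_1/2 equals the target
  model <- heterogeneity_model(mu0, sigma, T)
  fit <- hill_fit(binding_isotherm(T, grid, ensemble_isotherm(model, grid),
                                   kind = "fraction"))
  mu <- mu0 + R * T * log(target_Khalf / fit$K_half)
  model <- heterogeneity_model(mu, sigma, T)
  fit <- hill_fit(binding_isotherm(T, grid, ensemble_isotherm(model, grid),
                                   kind = "fraction"))
  structure(
    list(model = model, sigma = sigma, mu_dG = mu,
         achieved_nH = fit$n_H, achieved_Khalf = fit$K_half, grid = grid),
    class = "sigma_inference"
  )
}

#' @export
print.sigma_inference <- function(x, ...) {
  cat(sprintf(
    "<sigma_inference> sigma = %.2f kJ/mol, mu = %.2f kJ/mol (T = %.1f K)\n",
    x$sigma, x$mu_dG, x$model$T))
  cat(sprintf("  achieved n_H = %.3f, K_1/2 = %.3g M\n",
              x$achieved_nH, x$achieved_Khalf))
  invisible(x)
}
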