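# Variable-barrier (Landau) model of a continuous conformational transition.
#
# Enthalpy H is the order parameter. The free-energy functional at the
# characteristic temperature T0 is an asymmetric quartic,
#   G0(H) = -2*beta*(H/a)^2 + |beta|*(H/a)^4 ,  a = a1 (H < 0), a2 (H >= 0),
# with a1 + a2 = sum_alpha and asymmetry f = min(a1, a2)/max(a1, a2).
# beta < 0 gives a single minimum (downhill, second-order-like); beta > 0 a
# barrier. Temperatures away from T0 reweight the microstates through a
# temperature-independent entropy functional S0(H) = (H - G0(H))/T0, i.e.
#   P(H, T) proportional to exp{ S0(H)/R - H/(R T) } ,
# which reduces to exp{-G0/(R T0)} at T0 and makes the thermodynamic
# identity Cp(T) = d<H>/dT = (<H^2> - <H>^2)/(R T^2) exact.

#' Variable-barrier model parameters
#'
#' @param sum_alpha total enthalpy scale \eqn{\Sigma\alpha} in kJ mol^-1
#'   (> 0); splits into the low- and high-enthalpy lobe scales.
#' @param beta curvature parameter in kJ mol^-1; negative for downhill
#'   (barrierless) profiles, positive for barrier-limited ones.
#' @param T0 characteristic temperature in K (> 0).
#' @param f asymmetry factor in (0, 1]: the ratio of the smaller to the
#'   larger lobe scale.
#' @param big_lobe which side carries the larger lobe; `"high"` (default)
#'   puts the wider lobe at positive enthalpy, matching positively skewed
#'   enthalpy densities.
#' @param span_multiplier half-width of the enthalpy grid in units of
#'   `sum_alpha`.
#' @param n_grid number of enthalpy grid points.
#' @return an object of class `vb_params`.
#' @export
vb_params <- function(sum_alpha, beta, T0, f,
                      big_lobe = c("high", "low"),
                      span_multiplier = 2.5, n_grid = 2001L) {
  big_lobe <- match.arg(big_lobe)
  stopifnot(sum_alpha > 0, T0 > 0, f > 0, f <= 1,
            span_multiplier > 0, n_grid >= 101L)
  structure(
    list(sum_alpha = sum_alpha, beta = beta, T0 = T0, f = f,
         big_lobe = big_lobe, span_multiplier = span_multiplier,
         n_grid = as.integer(n_grid)),
    class = "vb_params"
  )
}

#' @export
print.vb_params <- function(x, ...) {
  cat(sprintf(
    "<vb_params> sum_alpha = %.1f kJ/mol, beta = %.1f kJ/mol, T0 = %.1f K, f = %.3f\n",
    x$sum_alpha, x$beta, x$T0, x$f))
  invisible(x)
}

# lobe scales: a_low for H < 0, a_high for H >= 0
vb_lobes <- function(params) {
  big <- params$sum_alpha / (1 + params$f)
  small <- params$sum_alpha - big
  if (params$big_lobe == "high") c(low = small, high = big)
  else c(low = big, high = small)
}

# G0 and S0 on an enthalpy grid
vb_functional <- function(params, span = params$span_multiplier) {
  H <- seq(-span * params$sum_alpha, span * params$sum_alpha,
           length.out = params$n_grid)
  lob <- vb_lobes(params)
  a <- ifelse(H < 0, lob["low"], lob["high"])
  x <- H / a
  G0 <- -2 * params$beta * x^2 + abs(params$beta) * x^4
  list(H = H, G0 = G0, S0_over_R = (H - G0) / (idp_constants$R * params$T0))
}

vb_weights <- function(fun, T) {
  lw <- fun$S0_over_R - fun$H / (idp_constants$R * T)
  w <- exp(lw - max(lw))
  Z <- pracma::trapz(fun$H, w)
  w / Z
}

#' Enthalpy probability density of the variable-barrier model
#'
#' Evaluates the normalized microstate density \eqn{P(H, T)} on the model's
#' enthalpy grid. If more than 1e-6 of the probability mass sits in the
#' outermost grid cells, the grid is widened once (doubled span); if the
#' widened grid still leaks, an error is raised.
#'
#' @param params a [vb_params()] object.
#' @param T temperature in K (scalar).
#' @return an object of class `enthalpy_density`: list with `H`
#'   (kJ mol^-1), `P` (density per kJ mol^-1, integrating to 1), `T`.
#' @export
vb_density <- function(params, T) {
  stopifnot(inherits(params, "vb_params"), length(T) == 1L, T > 0)
  span <- params$span_multiplier
  for (attempt in 1:2) {
    fun <- vb_functional(params, span)
    P <- vb_weights(fun, T)
    dH <- fun$H[2] - fun$H[1]
    edge_mass <- (P[1] + P[length(P)]) * dH
    if (edge_mass <= 1e-6) {
      return(structure(list(H = fun$H, P = P, T = T),
                       class = "enthalpy_density"))
    }
    span <- span * 2
  }
  stop(sprintf(
    "vb_density: probability mass %.3g at grid edges even after widening; enlarge span_multiplier",
    edge_mass), call. = FALSE)
}

#' @export
print.enthalpy_density <- function(x, ...) {
  cat(sprintf("<enthalpy_density> T = %.1f K, %d grid points, <H> = %.1f kJ/mol\n",
              x$T, length(x$H), pracma::trapz(x$H, x$H * x$P)))
  invisible(x)
}

# first two central moments of a density object
density_moments <- function(d) {
  m1 <- pracma::trapz(d$H, d$H * d$P)
  m2 <- pracma::trapz(d$H, d$H^2 * d$P)
  c(mean = m1, var = m2 - m1^2)
}

#' Mean enthalpy of the variable-barrier ensemble
#'
#' @param params a [vb_params()] object.
#' @param T temperature grid in K.
#' @return mean enthalpy in kJ mol^-1 at each temperature.
#' @export
vb_mean_enthalpy <- function(params, T) {
  vapply(T, function(Ti) density_moments(vb_density(params, Ti))["mean"],
         numeric(1))
}

#' Excess heat capacity of the variable-barrier model
#'
#' \eqn{C_{p,exc}(T) = (\langle H^2\rangle - \langle H\rangle^2)/(R T^2)}
#' from the moments of [vb_density()]. Under the model's entropy
#' construction this coincides with \eqn{d\langle H\rangle/dT}.
#'
#' @param params a [vb_params()] object.
#' @param T temperature grid in K.
#' @return excess heat capacity in kJ mol^-1 K^-1 at each temperature.
#' @export
vb_cp <- function(params, T) {
  vapply(T, function(Ti) {
    v <- density_moments(vb_density(params, Ti))["var"]
    unname(v) / (idp_constants$R * Ti^2)
  }, numeric(1))
}

# parameter transform for unconstrained optimization:
# (log sum_alpha, log(-beta) for downhill, T0, logit f)
vb_pack <- function(params) {
  c(log(params$sum_alpha),
    log(abs(params$beta)) * sign(params$beta),
    params$T0,
    stats::qlogis(min(params$f, 1 - 1e-9)))
}

vb_unpack <- function(p, template) {
  vb_params(sum_alpha = exp(p[1]),
            beta = sign(p[2]) * exp(abs(p[2])),
            T0 = p[3],
            f = stats::plogis(p[4]),
            big_lobe = template$big_lobe,
            span_multiplier = template$span_multiplier,
            n_grid = template$n_grid)
}

#' Fit the variable-barrier model to an excess heat-capacity curve
#'
#' Least-squares fit of [vb_cp()] to a measured excess heat-capacity curve
#' (or the `cp_excess` component of an [absolute_cp()] result) using
#' Levenberg-Marquardt with multistart: each start perturbs the initial
#' parameters by up to +/-20% (seed-controlled), and the best converged
#' start wins. Parameters are optimized as (log Sigma-alpha,
#' signed-log beta, T0, logit f) so the scale stays positive and the
#' asymmetry stays in (0, 1].
#'
#' @param T temperature grid in K.
#' @param cp_excess excess heat capacity in kJ mol^-1 K^-1.
#' @param init initial [vb_params()].
#' @param multistart number of perturbed starts (default 5).
#' @param seed integer seed for the start perturbations.
#' @return an object of class `vb_fit`: list with `params` (best-fit
#'   [vb_params()]), `deviance`, `residuals`, and `starts` (per-start
#'   data.frame of initial values, deviance and convergence flag).
#' @export
vb_fit <- function(T, cp_excess, init, multistart = 5L, seed = 1L) {
  stopifnot(inherits(init, "vb_params"), length(T) == length(cp_excess),
            length(T) >= 8L, multistart >= 1L)
  resid_fn <- function(p) {
    pr <- try(vb_unpack(p, init), silent = TRUE)
    if (inherits(pr, "try-error")) return(rep(1e6, length(T)))
    cp <- try(vb_cp(pr, T), silent = TRUE)
    if (inherits(cp, "try-error")) return(rep(1e6, length(T)))
    cp - cp_excess
  }
  p_init <- vb_pack(init)
  raw <- c(init$sum_alpha, init$beta, init$T0, init$f)
  perturb <- withr::with_seed(seed, {
    lapply(seq_len(multistart), function(i) {
      if (i == 1L) raw else raw * stats::runif(4, 0.8, 1.2)
    })
  })
  runs <- lapply(perturb, function(rw) {
    p0 <- vb_pack(vb_params(rw[1], rw[2], rw[3], min(rw[4], 1),
                            big_lobe = init$big_lobe,
                            span_multiplier = init$span_multiplier,
                            n_grid = init$n_grid))
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      list(ok = FALSE, deviance = Inf, fit = NULL, start = rw)
    } else {
      list(ok = fit$info %in% 1:4, deviance = fit$deviance,
           fit = fit, start = rw)
    }
  })
  dev <- vapply(runs, function(r) r$deviance, numeric(1))
  if (!any(is.finite(dev))) {
    diag <- paste(vapply(seq_along(runs), function(i)
      sprintf("start %d: deviance = %g", i, runs[[i]]$deviance), character(1)),
      collapse = "; ")
    stop("vb_fit: no multistart converged (", diag, ")", call. = FALSE)
  }
  best <- runs[[which.min(dev)]]
  params <- vb_unpack(best$fit$par, init)
  starts <- do.call(rbind, lapply(runs, function(r)
    data.frame(sum_alpha0 = r$start[1], beta0 = r$start[2],
               T00 = r$start[3], f0 = r$start[4],
               deviance = r$deviance, converged = r$ok)))
  structure(
    list(params = params, deviance = best$deviance,
         residuals = resid_fn(best$fit$par), starts = starts,
         T = T, cp_excess = cp_excess),
    class = "vb_fit"
  )
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("<vb_fit>\n  best parameters:\n")
  cat(sprintf(
    "    sum_alpha = %.1f kJ/mol, beta = %.1f kJ/mol, T0 = %.2f K, f = %.3f\n",
    x$params$sum_alpha, x$params$beta, x$params$T0, x$params$f))
  cat(sprintf("  deviance = %.4g over %d points; %d/%d starts converged\n",
              x$deviance, length(x$T), sum(x$starts$converged),
              nrow(x$starts)))
  invisible(x)
}
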