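# Hydrodynamics: DLS diffusion series -> hydrodynamic radii -> radius of
# gyration, plus polymer scaling laws for disordered chains.

#' Diffusion series at one temperature
#'
#' Container for dynamic light scattering results at a single temperature:
#' translational diffusion coefficients measured at one or more protein
#' concentrations.
#'
#' @param T temperature in K (scalar).
#' @param concentration protein concentrations in mg mL^-1 (non-negative).
#' @param D translational diffusion coefficients in m^2 s^-1 (positive),
#'   same length as `concentration`.
#' @return an object of class `diffusion_series`.
#' @export
diffusion_series <- function(T, concentration, D) {
  stopifnot(length(T) == 1L, is.finite(T), T > 0)
  if (length(concentration) < 1L || length(concentration) != length(D)) {
    stop("diffusion_series: need >= 1 (concentration, D) pair of equal length",
         call. = FALSE)
  }
  if (any(concentration < 0)) {
    stop("diffusion_series: concentrations must be non-negative", call. = FALSE)
  }
  if (any(D <= 0)) {
    stop("diffusion_series: diffusion coefficients must be positive", call. = FALSE)
  }
  structure(
    list(T = as.numeric(T),
         concentration = as.numeric(concentration),
         D = as.numeric(D)),
    class = "diffusion_series"
  )
}

#' @export
print.diffusion_series <- function(x, ...) {
  cat(sprintf("<diffusion_series> T = %.2f K, %d concentration(s)\n",
              x$T, length(x$concentration)))
  print(data.frame(concentration_mg_per_ml = x$concentration,
                   diffusion_m2_per_s = x$D))
  invisible(x)
}

#' Fit the concentration dependence of the diffusion coefficient
#'
#' Ordinary least squares fit of \eqn{D = D_0 (1 + a C)} to a diffusion
#' series, correcting for solution non-ideality. `D0` is the
#' infinite-dilution intercept and `a` the non-ideality coefficient in
#' mL mg^-1. A single-point series returns `D0 = D`, `a = 0` with a warning.
#'
#' @param series a [diffusion_series()].
#' @return an object of class `diffusion_fit` with elements `D0`, `a`,
#'   `residual_norm`, `T`, and `D_lowest_C` (the measured D at the lowest
#'   concentration, retained because either quantity can seed the
#'   Stokes-Einstein step; see [dls_to_radii()]).
#' @export
fit_diffusion_series <- function(series) {
  stopifnot(inherits(series, "diffusion_series"))
  C <- series$concentration
  D <- series$D
  D_low <- D[which.min(C)]
  if (length(unique(C)) < 2L) {
    warning("fit_diffusion_series: single concentration; returning D0 = D, a = 0",
            call. = FALSE)
    fit <- list(D0 = mean(D), a = 0,
                residual_norm = sqrt(sum((D - mean(D))^2)))
  } else {
    co <- stats::lm.fit(cbind(1, C), D)
    D0 <- unname(co$coefficients[1])
    slope <- unname(co$coefficients[2])
    fit <- list(D0 = D0, a = slope / D0,
                residual_norm = sqrt(sum(co$residuals^2)))
  }
  fit$T <- series$T
  fit$D_lowest_C <- D_low
  structure(fit, class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> T = %.2f K: D0 = %.4g m2/s, a = %.4g mL/mg (|r| = %.3g)\n",
              x$T, x$D0, x$a, x$residual_norm))
  invisible(x)
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' \eqn{R_h = k_B T / (6 \pi \eta(T) D_0)}, with the water viscosity taken
#' from [water_viscosity()].
#'
#' @param D0 infinite-dilution diffusion coefficient in m^2 s^-1 (> 0).
#' @param T temperature in K.
#' @return hydrodynamic radius in Angstrom.
#' @seealso [stokes_einstein_d0()] for the inverse map.
#' @export
stokes_einstein_rh <- function(D0, T) {
  stopifnot(all(D0 > 0))
  r_m <- idp_constants$kB * T / (6 * pi * water_viscosity(T) * D0)
  r_m * 1e10
}

#' Diffusion coefficient of a sphere of given hydrodynamic radius
#'
#' Inverse of [stokes_einstein_rh()]; used by the synthetic DLS generator.
#'
#' @param Rh hydrodynamic radius in Angstrom (> 0).
#' @param T temperature in K.
#' @return diffusion coefficient in m^2 s^-1.
#' @export
stokes_einstein_d0 <- function(Rh, T) {
  stopifnot(all(Rh > 0))
  idp_constants$kB * T / (6 * pi * water_viscosity(T) * (Rh * 1e-10))
}

#' Constants of the disordered-chain Rg/Rh conversion
#'
#' The ratio \eqn{\alpha = R_G/R_h} of a disordered chain of N residues is
#' modelled as a linear function of \eqn{R_G} interpolating between the
#' globule and coil size scalings:
#' \deqn{\alpha(R_G, N) = a_1 (R_G - a_2 N^{0.33}) / (N^{0.60} - N^{0.33}) + a_3}
#' with defaults \eqn{a_1 = 0.216} A^-1, \eqn{a_2 = 4.06} A,
#' \eqn{a_3 = 0.821}. The exponents 0.33 and 0.60 are literal constants of
#' the empirical form, not 1/3 and 3/5.
#'
#' @return a named list with `a1`, `a2`, `a3`.
#' @export
chain_conversion_constants <- function() {
  list(a1 = 0.216, a2 = 4.06, a3 = 0.821)
}

alpha_rg_rh <- function(Rg, N, const) {
  const$a1 * (Rg - const$a2 * N^0.33) / (N^0.60 - N^0.33) + const$a3
}

#' Convert radius of gyration to hydrodynamic radius for a disordered chain
#'
#' Applies the empirical \eqn{\alpha = R_G/R_h} ratio of
#' [chain_conversion_constants()]: \eqn{R_h = R_G / \alpha(R_G, N)}.
#'
#' @param Rg radius of gyration in Angstrom (> 0).
#' @param N number of residues (>= 2).
#' @param const conversion constants, see [chain_conversion_constants()].
#' @return hydrodynamic radius in Angstrom.
#' @export
rg_to_rh <- function(Rg, N, const = chain_conversion_constants()) {
  stopifnot(all(Rg > 0), N >= 2)
  Rg / alpha_rg_rh(Rg, N, const)
}

#' Convert hydrodynamic radius to radius of gyration for a disordered chain
#'
#' Numerical inverse of [rg_to_rh()] by bracketed root finding on the
#' physically monotone branch \eqn{R_G \in [2, 5 N^{0.6}]} Angstrom.
#'
#' @param Rh hydrodynamic radius in Angstrom (> 0).
#' @param N number of residues (>= 2).
#' @param const conversion constants, see [chain_conversion_constants()].
#' @return radius of gyration in Angstrom.
#' @export
rh_to_rg <- function(Rh, N, const = chain_conversion_constants()) {
  stopifnot(all(Rh > 0), N >= 2)
  lo <- 2
  hi <- 5 * N^0.6
  vapply(Rh, function(rh) {
    g <- function(Rg) rg_to_rh(Rg, N, const) - rh
    if (g(lo) * g(hi) > 0) {
      stop(sprintf(
        "rh_to_rg: no root for Rh = %g A in bracket [%g, %g] A (N = %d)",
        rh, lo, hi, as.integer(N)), call. = FALSE)
    }
    stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Flory scaling law for chain dimensions
#'
#' \eqn{R_G = \rho_0 N^{\nu}}. The Flory exponent is 1/3 for a compact
#' globule, 1/2 at the Theta point (ideal chain) and 3/5 for a swollen coil;
#' values outside \[1/3, 3/5\] are allowed but flagged with a warning.
#'
#' @param N number of residues (>= 1).
#' @param rho0 prefactor in Angstrom (default 2.2, the Theta-state value for
#'   disordered proteins).
#' @param nu Flory exponent (default 1/2).
#' @return radius of gyration in Angstrom.
#' @examples
#' scaling_rg(66) # ~17.9 A, ideal-chain expectation for a 66-residue IDP
#' @export
scaling_rg <- function(N, rho0 = 2.2, nu = 0.5) {
  stopifnot(all(N >= 1), rho0 > 0)
  if (nu < 1 / 3 || nu > 3 / 5) {
    warning(sprintf("scaling_rg: nu = %g outside the physical range [1/3, 3/5]", nu),
            call. = FALSE)
  }
  rho0 * N^nu
}

#' Percent compaction between two radii
#'
#' \eqn{100 (R_a - R_b) / R_a}: the relative size difference between a
#' reference state (for example the fully collapsed globule) and a second
#' state (for example the folded, DNA-bound form).
#'
#' @param Rh_a reference radius in Angstrom (> 0).
#' @param Rh_b comparison radius in Angstrom.
#' @return percent difference.
#' @export
percent_compaction <- function(Rh_a, Rh_b) {
  stopifnot(all(Rh_a > 0))
  100 * (Rh_a - Rh_b) / Rh_a
}

#' DLS pipeline: diffusion series to chain radii
#'
#' For each temperature, fits the non-ideality model
#' \eqn{D = D_0(1 + aC)}, converts to a hydrodynamic radius via
#' Stokes-Einstein, and (optionally) to a radius of gyration with the
#' disordered-chain conversion. Either the fitted intercept `D0` or the
#' measured D at the lowest concentration can seed the Stokes-Einstein step;
#' the intercept is the default since it removes non-ideality exactly.
#'
#' @param series_list a list of [diffusion_series()] objects.
#' @param N residue count for the Rg conversion; `NA` skips the conversion.
#' @param use `"D0"` (default) or `"lowestC"`.
#' @return a data.frame with columns `temperature_K`, `D0`, `a`, `Rh_A`,
#'   `Rg_A`.
#' @export
dls_to_radii <- function(series_list, N = NA, use = c("D0", "lowestC")) {
  use <- match.arg(use)
  stopifnot(length(series_list) >= 1L)
  rows <- lapply(series_list, function(s) {
    fit <- fit_diffusion_series(s)
    D_use <- if (use == "D0") fit$D0 else fit$D_lowest_C
    Rh <- stokes_einstein_rh(D_use, s$T)
    Rg <- if (is.na(N)) NA_real_ else rh_to_rg(Rh, N)
    data.frame(temperature_K = s$T, D0 = fit$D0, a = fit$a,
               Rh_A = Rh, Rg_A = Rg)
  })
  out <- do.call(rbind, rows)
  out[order(out$temperature_K), , drop = FALSE]
}
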