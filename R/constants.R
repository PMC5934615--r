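# Physical constants used throughout. Units are part of the API contract:
# diffusion coefficients in m^2 s^-1, radii in Angstrom at API boundaries,
# energies in kJ mol^-1, temperatures in K.

#' Physical constants
#'
#' Constants used by the hydrodynamics, calorimetry and binding modules.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, J K^-1.}
#'   \item{R}{Gas constant, kJ mol^-1 K^-1.}
#' }
#' @export
idp_constants <- list(
  kB = 1.380649e-23,
  R  = 8.314e-3
)

#' Temperature-dependent viscosity of water
#'
#' Empirical Vogel-type correlation
#' \eqn{\eta(T) = 2.414 \times 10^{-5} \cdot 10^{247.8/(T - 140)}} Pa s,
#' valid between the freezing and boiling points of water at ambient
#' pressure. Isolated in one function so an alternative correlation can be
#' substituted without touching the Stokes-Einstein pipeline.
#'
#' @param T temperature in K; must satisfy 273 < T < 373.
#' @return dynamic viscosity in Pa s.
#' @examples
#' water_viscosity(293.15) # ~1.002e-3
#' @export
water_viscosity <- function(T) {
  stopifnot(is.numeric(T))
  if (any(T <= 273 | T >= 373)) {
    stop("water_viscosity: T must lie in (273, 373) K", call. = FALSE)
  }
  2.414e-5 * 10^(247.8 / (T - 140))
}

#' Density of water
#'
#' Kell (1975) polynomial for the density of air-free water at 1 atm,
#' in g mL^-1. Used in the displaced-buffer correction that converts
#' apparent calorimetric heat capacities to absolute specific heats.
#'
#' @param T temperature in K.
#' @return density in g mL^-1.
#' @export
water_density <- function(T) {
  tc <- T - 273.15
  (999.83952 + 16.945176 * tc - 7.9870401e-3 * tc^2 -
     46.170461e-6 * tc^3 + 105.56302e-9 * tc^4 -
     280.54253e-12 * tc^5) / (1 + 16.879850e-3 * tc) / 1000
}

#' Specific heat capacity of water
#'
#' Smooth polynomial approximation to the isobaric specific heat of liquid
#' water (J g^-1 K^-1) between 273 and 373 K. The same function is used by
#' the thermogram generator and the absolute-heat-capacity extraction, so
#' the displaced-buffer correction is an exact round trip.
#'
#' @param T temperature in K.
#' @return specific heat in J g^-1 K^-1.
#' @export
water_specific_heat <- function(T) {
  tc <- T - 273.15
  4.2174 - 2.2619e-3 * tc + 4.9930e-5 * tc^2 -
    4.8181e-7 * tc^3 + 2.1936e-9 * tc^4
}
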