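# Absolute heat capacity from concentration-series DSC.
#
# The instrument measures, per scan, an apparent heat-capacity difference
# between the protein-filled and buffer-filled cell (J K^-1). Protein
# displaces its own volume of buffer, so at each temperature
#   dCp_app(T) = m_P * [c_p,P(T) - vbar * rho_w(T) * c_p,w(T)]
# with m_P the protein mass in the cell. Regressing dCp_app against m_P over
# a concentration series gives the slope s(T) = c_p,P - vbar*rho_w*c_p,w,
# from which the absolute specific heat (and molar heat capacity) follows.

#' Apparent heat-capacity thermogram at one concentration
#'
#' @param T strictly increasing temperature grid in K.
#' @param cp_app apparent (buffer-subtracted) heat capacity signal in J K^-1.
#' @param concentration_uM protein concentration in micromolar (scalar > 0).
#' @param scan_id optional scan identifier.
#' @return an object of class `cp_thermogram`.
#' @export
cp_thermogram <- function(T, cp_app, concentration_uM, scan_id = 1L) {
  stopifnot(length(T) == length(cp_app), length(T) >= 2L)
  if (any(diff(T) <= 0)) {
    stop("cp_thermogram: temperature grid must be strictly increasing",
         call. = FALSE)
  }
  stopifnot(length(concentration_uM) == 1L, concentration_uM > 0)
  structure(
    list(T = as.numeric(T), cp_app = as.numeric(cp_app),
         concentration_uM = as.numeric(concentration_uM),
         scan_id = scan_id),
    class = "cp_thermogram"
  )
}

#' @export
print.cp_thermogram <- function(x, ...) {
  cat(sprintf("<cp_thermogram> scan %s, %.1f uM, %d points over %.1f-%.1f K\n",
              as.character(x$scan_id), x$concentration_uM, length(x$T),
              min(x$T), max(x$T)))
  invisible(x)
}

#' Protein mass in the calorimeter cell
#'
#' @param concentration_uM molar concentration in micromolar.
#' @param molar_mass molar mass in g mol^-1.
#' @param cell_volume_mL active cell volume in mL (default 0.137, typical of
#'   capillary DSC cells).
#' @return mass in g.
#' @export
cell_protein_mass <- function(concentration_uM, molar_mass,
                              cell_volume_mL = 0.137) {
  concentration_uM * 1e-6 * molar_mass * cell_volume_mL * 1e-3
}

#' Absolute molar heat capacity from a DSC concentration series
#'
#' Per-temperature ordinary least-squares regression of the apparent
#' heat-capacity signal against the protein mass in the cell; the slope,
#' corrected for the displaced buffer, gives the absolute specific heat:
#' \eqn{c_p(T) = s(T) + \bar v \rho_w(T) c_{p,w}(T)}. Thermograms on
#' different temperature grids are interpolated onto their common overlap
#' (with a warning); extrapolation is refused.
#'
#' @param thermograms list of [cp_thermogram()] objects at >= 2 distinct
#'   concentrations.
#' @param molar_mass protein molar mass in g mol^-1.
#' @param partial_specific_volume partial specific volume in mL g^-1
#'   (default 0.73).
#' @param composition residue composition for the unfolded baseline
#'   (default [default_composition()]).
#' @param cell_volume_mL active cell volume in mL.
#' @return an object of class `absolute_cp_curve`: a list with `T`,
#'   `cp_abs`, `baseline_folded`, `baseline_unfolded`, `cp_excess`
#'   (all kJ mol^-1 K^-1) and `dH2` ((kJ mol^-1)^2). The excess heat
#'   capacity is the absolute curve minus the folded baseline.
#' @export
absolute_cp <- function(thermograms, molar_mass,
                        partial_specific_volume = 0.73,
                        composition = default_composition(),
                        cell_volume_mL = 0.137) {
  stopifnot(length(thermograms) >= 2L)
  concs <- vapply(thermograms, function(th) th$concentration_uM, numeric(1))
  if (length(unique(concs)) < 2L) {
    stop("absolute_cp: need >= 2 distinct concentrations to extract the slope",
         call. = FALSE)
  }
  grids <- lapply(thermograms, function(th) th$T)
  Tref <- grids[[1]]
  same_grid <- all(vapply(grids, function(g)
    length(g) == length(Tref) && all(g == Tref), logical(1)))
  if (!same_grid) {
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (lo >= hi) {
      stop("absolute_cp: thermogram temperature grids do not overlap",
           call. = FALSE)
    }
    warning("absolute_cp: regridding thermograms onto their common overlap",
            call. = FALSE)
    Tref <- Tref[Tref >= lo & Tref <= hi]
  }
  sig <- vapply(thermograms, function(th) {
    if (length(th$T) == length(Tref) && all(th$T == Tref)) th$cp_app
    else stats::approx(th$T, th$cp_app, xout = Tref)$y
  }, numeric(length(Tref)))
  mass <- cell_protein_mass(concs, molar_mass, cell_volume_mL)
  X <- cbind(1, mass)
  slopes <- vapply(seq_along(Tref), function(i) {
    unname(stats::lm.fit(X, sig[i, ])$coefficients[2])     # J g^-1 K^-1
  }, numeric(1))
  cp_spec <- slopes + partial_specific_volume * water_density(Tref) *
    water_specific_heat(Tref)                              # J g^-1 K^-1
  cp_abs <- cp_spec * molar_mass / 1000                    # kJ mol^-1 K^-1
  bf <- folded_baseline(Tref, molar_mass)
  bu <- unfolded_baseline(Tref, composition)
  cp_excess <- cp_abs - bf
  structure(
    list(T = Tref, cp_abs = cp_abs,
         baseline_folded = bf, baseline_unfolded = bu,
         cp_excess = cp_excess,
         dH2 = excess_fluctuations(cp_excess, Tref),
         molar_mass = molar_mass),
    class = "absolute_cp_curve"
  )
}

#' @export
print.absolute_cp_curve <- function(x, ...) {
  cat(sprintf("<absolute_cp_curve> %d points over %.1f-%.1f K\n",
              length(x$T), min(x$T), max(x$T)))
  cat(sprintf("  Cp_abs %.2f-%.2f kJ/mol/K; max dH2 = %.0f (kJ/mol)^2 at %.1f K\n",
              min(x$cp_abs), max(x$cp_abs), max(x$dH2), x$T[which.max(x$dH2)]))
  invisible(x)
}

#' Excess enthalpic fluctuations from the excess heat capacity
#'
#' The variance of the molar enthalpy distribution follows from the excess
#' heat capacity (absolute curve minus the folded baseline) through
#' \eqn{\delta H^2(T) = R T^2 C_{p,exc}(T)}, R = 8.314e-3 kJ mol^-1 K^-1.
#'
#' @param cp_excess excess heat capacity in kJ mol^-1 K^-1.
#' @param T matching temperature grid in K.
#' @return enthalpy variance in (kJ mol^-1)^2.
#' @export
excess_fluctuations <- function(cp_excess, T) {
  stopifnot(length(cp_excess) == length(T))
  idp_constants$R * T^2 * cp_excess
}
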