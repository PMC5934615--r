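# Synthetic instrument-data generators. Each generator is the exact inverse
# of its analysis stage at zero noise, so every downstream pipeline is
# testable end-to-end without instrument data. All randomness flows from a
# single integer seed per generator call; zero-noise calls never touch the
# RNG.

#' Additive-Gaussian noise specification
#'
#' @param sd noise standard deviation in the units of the signal it is
#'   added to (>= 0; 0 disables noise and leaves the RNG untouched).
#' @param seed integer seed; identical (parameters, seed) pairs give
#'   bitwise-identical output.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1L) {
  stopifnot(sd >= 0, length(seed) == 1L)
  structure(list(kind = "additive-gaussian", sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

add_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sd == 0) return(x)
  x + withr::with_seed(noise$seed, stats::rnorm(length(x), 0, noise$sd))
}

#' Coil-to-globule collapse scenario
#'
#' Defines the ground truth behind synthetic DLS data: linear hydrodynamic
#' radius baselines for the expanded coil (U_E) and collapsed globule (U_C)
#' mixed by a two-state van't Hoff equilibrium centred at the collapse
#' temperature. Defaults follow the regime of a small disordered domain:
#' 24 A coil, 17 A globule, T_c = 312 K, over 283-333 K every 10 K.
#'
#' @param T_grid measurement temperatures in K.
#' @param Rh_expanded coil baseline as c(intercept A, slope A/K).
#' @param Rh_collapsed globule baseline as c(intercept A, slope A/K); must
#'   stay below the coil baseline over the grid.
#' @param T_c collapse temperature in K, inside the grid.
#' @param dH_c van't Hoff enthalpy of the U_E <-> U_C equilibrium in
#'   kJ mol^-1 (default 150, a package default giving a transition width
#'   comparable to the DLS window).
#' @return an object of class `collapse_scenario`.
#' @export
collapse_scenario <- function(T_grid = seq(283, 333, by = 10),
                              Rh_expanded = c(24, 0),
                              Rh_collapsed = c(17, 0),
                              T_c = 312, dH_c = 150) {
  stopifnot(length(T_grid) >= 1L, dH_c > 0)
  rE <- Rh_expanded[1] + Rh_expanded[2] * T_grid
  rC <- Rh_collapsed[1] + Rh_collapsed[2] * T_grid
  if (any(rE <= rC)) {
    stop("collapse_scenario: expanded Rh must exceed collapsed Rh over the grid",
         call. = FALSE)
  }
  if (T_c < min(T_grid) || T_c > max(T_grid)) {
    stop("collapse_scenario: T_c must lie inside T_grid", call. = FALSE)
  }
  structure(list(T_grid = as.numeric(T_grid),
                 Rh_expanded = Rh_expanded, Rh_collapsed = Rh_collapsed,
                 T_c = T_c, dH_c = dH_c),
            class = "collapse_scenario")
}

#' Scenario hydrodynamic radius
#'
#' Population-weighted two-state mixture of the expanded and collapsed
#' baselines at the given temperatures.
#'
#' @param scenario a [collapse_scenario()].
#' @param T temperatures in K (default the scenario grid).
#' @return hydrodynamic radii in Angstrom.
#' @export
scenario_rh <- function(scenario, T = scenario$T_grid) {
  stopifnot(inherits(scenario, "collapse_scenario"))
  p <- two_state_pop(T, scenario$T_c, scenario$dH_c)
  rE <- scenario$Rh_expanded[1] + scenario$Rh_expanded[2] * T
  rC <- scenario$Rh_collapsed[1] + scenario$Rh_collapsed[2] * T
  p * rE + (1 - p) * rC
}

#' Generate synthetic DLS diffusion series
#'
#' For each scenario temperature, the infinite-dilution diffusion
#' coefficient is the Stokes-Einstein inverse of the scenario's mixed
#' hydrodynamic radius; concentration non-ideality enters as
#' \eqn{D = D_0 (1 + a C)}, and additive Gaussian noise (if any) is applied
#' to D.
#'
#' @param scenario a [collapse_scenario()].
#' @param concentrations positive protein concentrations in mg mL^-1
#'   (default 0.45, 0.90, 1.35).
#' @param a non-ideality coefficient in mL mg^-1 (default 0.01).
#' @param noise a [noise_spec()] in m^2 s^-1 units.
#' @return a list of [diffusion_series()], one per temperature.
#' @export
gen_dls_series <- function(scenario, concentrations = c(0.45, 0.90, 1.35),
                           a = 0.01, noise = noise_spec()) {
  stopifnot(inherits(scenario, "collapse_scenario"))
  if (length(concentrations) < 1L || any(concentrations <= 0)) {
    stop("gen_dls_series: concentrations must be non-empty and positive",
         call. = FALSE)
  }
  Rh <- scenario_rh(scenario)
  D0 <- stokes_einstein_d0(Rh, scenario$T_grid)
  D_mat <- outer(D0, 1 + a * concentrations)
  D_mat[] <- add_noise(as.numeric(D_mat), noise)
  lapply(seq_along(scenario$T_grid), function(i)
    diffusion_series(scenario$T_grid[i], concentrations, D_mat[i, ]))
}

#' Generate synthetic DSC thermograms
#'
#' Builds the true absolute molar heat capacity as folded baseline plus the
#' variable-barrier excess, converts it to per-cell apparent signals with
#' the displaced-buffer relation (the exact inverse of [absolute_cp()]),
#' and adds noise.
#'
#' @param vb a [vb_params()] object defining the excess heat capacity.
#' @param concentrations protein concentrations in uM (>= 2 distinct values
#'   for downstream extraction; a single value warns). Default c(52, 110).
#' @param T_grid temperature grid in K.
#' @param molar_mass protein molar mass in g mol^-1.
#' @param partial_specific_volume partial specific volume in mL g^-1.
#' @param cell_volume_mL calorimeter cell volume in mL.
#' @param noise a [noise_spec()] in J K^-1 units (applied per scan).
#' @return a list of [cp_thermogram()] objects, one per concentration.
#' @export
gen_thermograms <- function(vb, concentrations = c(52, 110),
                            T_grid = seq(278, 373, by = 1),
                            molar_mass = 7500,
                            partial_specific_volume = 0.73,
                            cell_volume_mL = 0.137,
                            noise = noise_spec()) {
  stopifnot(inherits(vb, "vb_params"))
  if (length(unique(concentrations)) < 2L) {
    warning("gen_thermograms: single concentration; absolute-Cp extraction downstream needs >= 2",
            call. = FALSE)
  }
  cp_abs <- folded_baseline(T_grid, molar_mass) + vb_cp(vb, T_grid)   # kJ/mol/K
  cp_spec <- cp_abs * 1000 / molar_mass                               # J/g/K
  buffer <- partial_specific_volume * water_density(T_grid) *
    water_specific_heat(T_grid)
  mass <- cell_protein_mass(concentrations, molar_mass, cell_volume_mL)
  sig <- outer(cp_spec - buffer, mass)                                # J/K
  sig[] <- add_noise(as.numeric(sig), noise)
  lapply(seq_along(concentrations), function(j)
    cp_thermogram(T_grid, sig[, j], concentrations[j], scan_id = j))
}

#' Generate a synthetic binding isotherm
#'
#' Computes the bulk fraction bound of a heterogeneity model on the titrant
#' grid, maps it to anisotropy, and adds noise.
#'
#' @param model a [heterogeneity_model()].
#' @param grid titrant concentrations in M (default
#'   [default_titration_grid()]).
#' @param r_free,r_bound anisotropy amplitudes (defaults 0.06 and 0.16,
#'   package defaults typical of a dye-labelled oligonucleotide reporter);
#'   `r_bound` must exceed `r_free`.
#' @param noise a [noise_spec()] in anisotropy units.
#' @return a [binding_isotherm()] of kind `"anisotropy"`.
#' @export
gen_binding_isotherms <- function(model, grid = default_titration_grid(),
                                  r_free = 0.06, r_bound = 0.16,
                                  noise = noise_spec()) {
  f <- ensemble_isotherm(model, grid)
  r <- anisotropy_from_fraction(f, r_free, r_bound)
  binding_isotherm(model$T, grid, add_noise(r, noise), kind = "anisotropy")
}

#' Default melt-probe parameters
#'
#' The three apparent midpoints used by the default synthetic melts:
#' fluorescence red shift at 301 K, near-UV CD at 307 K and the DLS size
#' transition at 312 K — an 11 K spread across probes, the signature of an
#' energetically decoupled continuous transition.
#'
#' @return a data.frame with columns `probe`, `T_m_K`, `dH_kJmol`.
#' @export
default_melt_probes <- function() {
  data.frame(
    probe = c("fluorescence_shift", "near_uv_cd", "dls_rh"),
    T_m_K = c(301, 307, 312),
    dH_kJmol = c(150, 150, 150),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic melting curve
#'
#' Population-weighted two-state mixture of linear state baselines plus
#' noise; the exact inverse of [two_state_fit()] at zero noise.
#'
#' @param T_m apparent midpoint in K.
#' @param dH_vH van't Hoff enthalpy in kJ mol^-1.
#' @param baseline_expanded,baseline_collapsed c(intercept, slope) of the
#'   two state baselines in signal units (vs K).
#' @param T_grid temperature grid in K (non-empty, >= 8 points).
#' @param probe probe label.
#' @param noise a [noise_spec()] in signal units.
#' @return a [probe_curve()].
#' @export
gen_melt_curve <- function(T_m, dH_vH,
                           baseline_expanded = c(1, -0.002),
                           baseline_collapsed = c(0.1, -0.0005),
                           T_grid = seq(278, 350, by = 2),
                           probe = "probe", noise = noise_spec()) {
  if (length(T_grid) == 0L) {
    stop("gen_melt_curve: empty temperature grid", call. = FALSE)
  }
  y <- two_state_signal(T_grid, T_m, dH_vH, baseline_expanded,
                        baseline_collapsed)
  probe_curve(T_grid, add_noise(y, noise), probe)
}

#' Generate a synthetic rank-2 spectral matrix
#'
#' Emission spectra modelled as a fixed mean band plus a red-shift mode
#' whose temperature amplitude follows the two-state population and changes
#' sign at the transition midpoint; the matrix is exactly rank 2 at zero
#' noise.
#'
#' @param wavelength wavelength grid in nm.
#' @param T_grid temperature grid in K (non-empty).
#' @param T_m midpoint of the spectral shift in K.
#' @param dH_vH van't Hoff enthalpy of the shift in kJ mol^-1.
#' @param peak_nm,width_nm centre and Gaussian width of the mean emission
#'   band.
#' @param shift_amplitude amplitude of the red-shift mode relative to the
#'   mean band (default 0.15).
#' @param noise a [noise_spec()] in signal units.
#' @return a [spectral_matrix()].
#' @export
gen_spectral_matrix <- function(wavelength = seq(280, 400, by = 2),
                                T_grid = seq(278, 350, by = 3),
                                T_m = 301, dH_vH = 150,
                                peak_nm = 303, width_nm = 18,
                                shift_amplitude = 0.15,
                                noise = noise_spec()) {
  if (length(T_grid) == 0L) {
    stop("gen_spectral_matrix: empty temperature grid", call. = FALSE)
  }
  u1 <- exp(-0.5 * ((wavelength - peak_nm) / width_nm)^2)
  u2 <- -(wavelength - peak_nm) / width_nm * u1   # red-shift (derivative) mode
  p <- two_state_pop(T_grid, T_m, dH_vH)
  v1 <- rep(1, length(T_grid))
  v2 <- shift_amplitude * (1 - 2 * p)             # sign change at T_m
  M <- outer(u1, v1) + outer(u2, v2)
  M[] <- add_noise(as.numeric(M), noise)
  spectral_matrix(wavelength, T_grid, M)
}
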