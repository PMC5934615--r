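# CSV interchange. One dialect per instrument series, header row with
# SI-annotated column names. Numeric columns are written with 17 significant
# digits so re-reading an output reproduces the in-memory values exactly.

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and write DLS diffusion data
#'
#' Columns: `temperature_K`, `concentration_mg_per_ml`,
#' `diffusion_m2_per_s`; one row per measurement.
#'
#' @param path CSV file path.
#' @return `read_dls_csv`: a list of [diffusion_series()], one per
#'   temperature, ordered by temperature.
#' @export
read_dls_csv <- function(path) {
  df <- read_checked_csv(path, c("temperature_K", "concentration_mg_per_ml",
                                 "diffusion_m2_per_s"))
  lapply(split(df, df$temperature_K), function(g)
    diffusion_series(g$temperature_K[1], g$concentration_mg_per_ml,
                     g$diffusion_m2_per_s))
}

#' @rdname read_dls_csv
#' @param series_list list of [diffusion_series()].
#' @export
write_dls_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(temperature_K = s$T, concentration_mg_per_ml = s$concentration,
               diffusion_m2_per_s = s$D)))
  write_csv_precise(df, path)
}

#' Read and write DSC thermograms
#'
#' Columns: `temperature_K`, `cp_apparent` (J K^-1, buffer-subtracted),
#' `concentration_uM`, `scan_id`.
#'
#' @param path CSV file path.
#' @return `read_dsc_csv`: a list of [cp_thermogram()], one per scan.
#' @export
read_dsc_csv <- function(path) {
  df <- read_checked_csv(path, c("temperature_K", "cp_apparent",
                                 "concentration_uM", "scan_id"))
  lapply(split(df, df$scan_id), function(g)
    cp_thermogram(g$temperature_K, g$cp_apparent, g$concentration_uM[1],
                  g$scan_id[1]))
}

#' @rdname read_dsc_csv
#' @param thermograms list of [cp_thermogram()].
#' @export
write_dsc_csv <- function(thermograms, path) {
  df <- do.call(rbind, lapply(thermograms, function(th)
    data.frame(temperature_K = th$T, cp_apparent = th$cp_app,
               concentration_uM = th$concentration_uM,
               scan_id = th$scan_id)))
  write_csv_precise(df, path)
}

#' Write an absolute heat-capacity curve
#'
#' Columns: `temperature_K`, `cp_abs`, `baseline_folded`,
#' `baseline_unfolded`, `cp_excess` (kJ mol^-1 K^-1) and `dH2`
#' ((kJ mol^-1)^2).
#'
#' @param curve an [absolute_cp()] result.
#' @param path CSV file path.
#' @export
write_absolute_cp_csv <- function(curve, path) {
  stopifnot(inherits(curve, "absolute_cp_curve"))
  write_csv_precise(data.frame(
    temperature_K = curve$T, cp_abs = curve$cp_abs,
    baseline_folded = curve$baseline_folded,
    baseline_unfolded = curve$baseline_unfolded,
    cp_excess = curve$cp_excess, dH2 = curve$dH2), path)
}

#' Read and write binding isotherms
#'
#' Columns: `temperature_K`, `cytr_conc_M`, `anisotropy`.
#'
#' @param path CSV file path.
#' @return `read_isotherm_csv`: a [binding_isotherm()] of kind
#'   `"anisotropy"`.
#' @export
read_isotherm_csv <- function(path) {
  df <- read_checked_csv(path, c("temperature_K", "cytr_conc_M", "anisotropy"))
  binding_isotherm(df$temperature_K[1], df$cytr_conc_M, df$anisotropy,
                   kind = "anisotropy")
}

#' @rdname read_isotherm_csv
#' @param isotherm a [binding_isotherm()].
#' @export
write_isotherm_csv <- function(isotherm, path) {
  write_csv_precise(data.frame(
    temperature_K = isotherm$T, cytr_conc_M = isotherm$conc,
    anisotropy = isotherm$signal), path)
}

#' Read and write melting curves
#'
#' Columns: `temperature_K`, `signal`, `probe`; one or more probes per
#' file.
#'
#' @param path CSV file path.
#' @return `read_melt_csv`: a list of [probe_curve()], one per probe.
#' @export
read_melt_csv <- function(path) {
  df <- read_checked_csv(path, c("temperature_K", "signal", "probe"))
  lapply(split(df, df$probe), function(g)
    probe_curve(g$temperature_K, g$signal, g$probe[1]))
}

#' @rdname read_melt_csv
#' @param curves list of [probe_curve()].
#' @export
write_melt_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(temperature_K = cv$T, signal = cv$signal, probe = cv$probe)))
  write_csv_precise(df, path)
}

#' Read and write spectral matrices
#'
#' First column `wavelength_nm`; each remaining column one temperature,
#' with the temperature in K as the column header.
#'
#' @param path CSV file path.
#' @return `read_spectra_csv`: a [spectral_matrix()].
#' @export
read_spectra_csv <- function(path) {
  df <- read_checked_csv(path, "wavelength_nm")
  Tcols <- setdiff(names(df), "wavelength_nm")
  Tvals <- suppressWarnings(as.numeric(Tcols))
  if (anyNA(Tvals)) {
    stop(path, ": non-numeric temperature column header(s)", call. = FALSE)
  }
  spectral_matrix(df$wavelength_nm, Tvals,
                  as.matrix(df[, Tcols, drop = FALSE]))
}

#' @rdname read_spectra_csv
#' @param mat a [spectral_matrix()].
#' @export
write_spectra_csv <- function(mat, path) {
  df <- data.frame(wavelength_nm = mat$wavelength)
  for (j in seq_along(mat$T)) df[[sprintf("%.17g", mat$T[j])]] <- mat$M[, j]
  write_csv_precise(df, path)
}
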