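# Empirical heat-capacity baselines for folded and unfolded proteins.
# Coefficients are nominal transcriptions of the published correlations
# (folded: linear specific heat; unfolded: composition-weighted per-residue
# heat capacities) shipped as editable defaults. No downstream result depends
# on their exact values; they bound and anchor the absolute Cp curve.

#' Coefficients of the folded-protein heat-capacity baseline
#'
#' Specific heat of a folded globular protein modelled as linear in
#' temperature: \eqn{c_p(T) = b_0 + b_1 (T - 273.15)} in J g^-1 K^-1.
#' Defaults give ~1.33 J g^-1 K^-1 at 298 K with slope 6.6e-3 J g^-1 K^-2,
#' typical of compact folded proteins.
#'
#' @return named list with `b0` (J g^-1 K^-1) and `b1` (J g^-1 K^-2).
#' @export
folded_baseline_coefficients <- function() {
  list(b0 = 1.172, b1 = 6.61e-3)
}

#' Folded-state heat-capacity baseline
#'
#' Linear-in-temperature specific heat multiplied by the molar mass, giving
#' the molar heat capacity of a hypothetical fully folded state.
#'
#' @param T temperature grid in K.
#' @param molar_mass protein molar mass in g mol^-1.
#' @param coef coefficients, see [folded_baseline_coefficients()].
#' @return molar heat capacity in kJ mol^-1 K^-1 on the grid.
#' @export
folded_baseline <- function(T, molar_mass, coef = folded_baseline_coefficients()) {
  stopifnot(molar_mass > 0)
  cp_specific <- coef$b0 + coef$b1 * (T - 273.15)   # J g^-1 K^-1
  cp_specific * molar_mass / 1000                   # kJ mol^-1 K^-1
}

#' Per-residue heat capacities of the unfolded state
#'
#' Tabulated heat-capacity contributions of each amino-acid residue
#' (backbone plus side chain) in the unfolded state, J mol^-1 K^-1, at six
#' anchor temperatures. Nominal values transcribed from the published
#' unfolded-state additivity scheme; intended as editable defaults whose
#' composition-weighted sum, interpolated in T, forms the unfolded baseline.
#'
#' @return a data.frame with column `residue` (one-letter code) and one
#'   column per anchor temperature (`T278` ... `T398`, K).
#' @export
mp_residue_cp <- function() {
  data.frame(
    residue = c("G", "A", "S", "T", "V", "L", "I", "P", "M", "F",
                "W", "Y", "C", "N", "Q", "D", "E", "K", "R", "H"),
    T278 = c( 81, 134, 118, 183, 256, 327, 337, 178, 290, 382,
             397, 297, 171, 122, 183, 110, 167, 301, 271, 201),
    T298 = c( 88, 146, 128, 199, 278, 355, 366, 193, 315, 415,
             432, 323, 186, 133, 199, 120, 182, 327, 295, 218),
    T323 = c( 95, 158, 138, 215, 300, 383, 395, 208, 340, 448,
             467, 349, 201, 144, 215, 130, 197, 353, 319, 235),
    T348 = c( 99, 165, 145, 225, 314, 401, 414, 218, 356, 469,
             488, 365, 210, 150, 225, 136, 206, 370, 333, 246),
    T373 = c(101, 168, 147, 229, 320, 408, 421, 222, 362, 477,
             497, 371, 214, 153, 229, 138, 209, 376, 339, 251),
    T398 = c(101, 168, 147, 229, 320, 408, 421, 222, 362, 477,
             497, 371, 214, 153, 229, 138, 209, 376, 339, 251),
    stringsAsFactors = FALSE
  )
}

mp_anchor_temperatures <- function() c(278.15, 298.15, 323.15, 348.15, 373.15, 398.15)

#' Unfolded-state heat-capacity baseline
#'
#' Composition-weighted sum of tabulated per-residue unfolded-state heat
#' capacities, interpolated in temperature (natural spline through the six
#' tabulated anchors).
#'
#' @param T temperature grid in K.
#' @param composition named integer vector of residue counts, names being
#'   one-letter amino-acid codes present in [mp_residue_cp()].
#' @param table per-residue coefficient table, see [mp_residue_cp()].
#' @return molar heat capacity in kJ mol^-1 K^-1 on the grid.
#' @export
unfolded_baseline <- function(T, composition, table = mp_residue_cp()) {
  stopifnot(length(composition) >= 1L, !is.null(names(composition)))
  unknown <- setdiff(names(composition), table$residue)
  if (length(unknown)) {
    stop("unfolded_baseline: unknown residue code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  anchors <- mp_anchor_temperatures()
  mat <- as.matrix(table[, -1])
  rownames(mat) <- table$residue
  counts <- composition[rownames(mat)]
  counts[is.na(counts)] <- 0
  cp_anchor <- as.numeric(counts %*% mat)          # J mol^-1 K^-1 at anchors
  fun <- stats::splinefun(anchors, cp_anchor, method = "natural")
  fun(T) / 1000                                    # kJ mol^-1 K^-1
}

#' A generic disordered-domain residue composition
#'
#' Default 66-residue composition used by the synthetic-data module when a
#' real sequence is not supplied: a hydrophilic-leaning mixture typical of a
#' small helical DNA-binding domain. Synthetic stand-in, not a real sequence.
#'
#' @return named integer vector of residue counts summing to 66.
#' @export
default_composition <- function() {
  c(G = 5, A = 7, S = 5, T = 4, V = 4, L = 6, I = 3, P = 2, M = 1,
    F = 2, W = 0, Y = 1, C = 0, N = 3, Q = 4, D = 4, E = 6, K = 5,
    R = 3, H = 1)
}
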