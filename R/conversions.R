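#' Convert Walkley-Black soil carbon to Dumas-equivalent carbon
#'
#' Soil organic carbon measured by wet oxidation (Walkley-Black) underestimates
#' total carbon relative to dry combustion (Dumas/Leco). Measurements from the
#' two methods are reconciled with the linear calibration
#' \eqn{C_{Dumas} = 0.126 + 1.25 C_{WB}}.
#'
#' @param c_wb Walkley-Black carbon, percent by mass. Must be non-negative.
#' @return Dumas-equivalent carbon, percent by mass.
#' @examples
#' walkley_black_to_dumas(1.0)  # 1.376
#' @export
walkley_black_to_dumas <- function(c_wb) {
  stopifnot(is.numeric(c_wb))
  if (any(c_wb < 0, na.rm = TRUE)) {
    stop("Walkley-Black carbon must be non-negative")
  }
  0.126 + 1.25 * c_wb
}

#' Convert pH measured in CaCl2 to pH in water
#'
#' Soil pH read in a 0.01 M CaCl2 suspension runs lower than pH in water; the
#' standard calibration is \eqn{pH_{water} = 0.27 + 1.03 pH_{CaCl2}}.
#'
#' @param ph pH in CaCl2, restricted to the plausible soil range \[2, 10\].
#' @return pH in water.
#' @export
ph_cacl2_to_water <- function(ph) {
  stopifnot(is.numeric(ph))
  if (any(ph < 2 | ph > 10, na.rm = TRUE)) {
    stop("pH must lie in [2, 10]")
  }
  0.27 + 1.03 * ph
}

#' Convert Bray-2 extractable phosphorus to Mehlich-3 equivalent
#'
#' Uses the calibration \eqn{P_{M3} = -34.6 + 0.86 P_{Bray2}} (mg kg-1).
#' The line crosses zero near 40.2 mg kg-1, so low Bray-2 readings map to
#' non-physical negative concentrations; those are floored at `floor_value`
#' (which keeps downstream log-ratios defined) and flagged in the
#' `"floored"` attribute of the result.
#'
#' @param p_bray2 Bray-2 phosphorus, mg kg-1, non-negative.
#' @param floor_value Positive floor applied to converted values, mg kg-1.
#' @return Mehlich-3 phosphorus, mg kg-1, with a logical attribute `floored`.
#' @export
bray2_to_mehlich3 <- function(p_bray2, floor_value = 1) {
  stopifnot(is.numeric(p_bray2), floor_value > 0)
  if (any(p_bray2 < 0, na.rm = TRUE)) {
    stop("Bray-2 phosphorus must be non-negative")
  }
  raw <- -34.6 + 0.86 * p_bray2
  flo <- !is.na(raw) & raw < floor_value
  out <- pmax(raw, floor_value)
  attr(out, "floored") <- flo
  out
}

#' Tuber specific gravity from weights in air and in water
#'
#' \eqn{SG = W_{air} / (W_{air} - W_{water})}. The ratio is invariant to the
#' sample size, so any consistent mass unit may be used.
#'
#' @param weight_air Weight of the tuber sample in air, g.
#' @param weight_water Weight of the same sample submerged in water, g.
#' @return Specific gravity (unitless, > 1 for sinking tubers).
#' @export
specific_gravity <- function(weight_air, weight_water) {
  stopifnot(is.numeric(weight_air), is.numeric(weight_water))
  if (any(weight_water < 0, na.rm = TRUE) ||
      any(weight_air <= weight_water, na.rm = TRUE)) {
    stop("need weight_air > weight_water >= 0 (non-physical weights)")
  }
  weight_air / (weight_air - weight_water)
}

#' Convert elemental P and K doses to oxide basis
#'
#' Fertilizer labels express P as P2O5 and K as K2O; elemental doses are
#' converted by the stoichiometric factors 2.291 (P) and 1.205 (K).
#'
#' @param dose_P,dose_K Elemental doses, kg ha-1, non-negative.
#' @return A list with components `P2O5` and `K2O`, kg ha-1.
#' @export
elemental_to_oxide <- function(dose_P, dose_K) {
  if (any(dose_P < 0, na.rm = TRUE) || any(dose_K < 0, na.rm = TRUE)) {
    stop("doses must be non-negative")
  }
  list(P2O5 = 2.291 * dose_P, K2O = 1.205 * dose_K)
}

#' Phosphorus saturation environmental risk index
#'
#' The (P/Al) Mehlich-3 index, in percent: \eqn{100 \cdot P_{M3} / Al_{M3}}.
#' Values are reported to one decimal, the convention used for environmental
#' risk classes (e.g. about 1.5 percent = extremely low, 11 = medium, 29 = very
#' high risk of P loss).
#'
#' @param p_m3 Mehlich-3 phosphorus, mg kg-1.
#' @param al_m3 Mehlich-3 aluminium, mg kg-1, strictly positive.
#' @return Index in percent, rounded to one decimal.
#' @export
phosphorus_saturation_index <- function(p_m3, al_m3) {
  stopifnot(is.numeric(p_m3), is.numeric(al_m3))
  if (any(al_m3 <= 0, na.rm = TRUE)) {
    stop("Mehlich-3 Al must be strictly positive")
  }
  round(100 * p_m3 / al_m3, 1)
}
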