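#' Published reference cells for shallow-water detonation exposure
#'
#' Eight published scenario cells — sound exposure level (SEL, dB re
#' 1 uPa^2 s, integrated over the period containing 90% of the waveform)
#' and peak pressure (Pa) for nominal 5 lb and 20 lb C4 charges at ranges
#' of 1, 3, 6 and 12 km — computed from a semi-empirical similitude model
#' for underwater detonations in shallow water measured near the training
#' range. They anchor the single-constant calibration of [sel_db()] and
#' validate [peak_pressure()].
#'
#' A note on units: back-solving these cells is consistent with plugging
#' the nominal printed charge weight directly into the similitude
#' formulas; it is not consistent with a kg-TNT conversion at any standard
#' equivalence factor, even though such a conversion is nominally implied.
#' The functions therefore treat `weight` as the as-printed numeric value
#' by default; [lb_c4_to_kg_tnt()] is provided for physically explicit use.
#'
#' @return data.frame with `range_km`, `charge_lb`, `sel_db`, `peak_pa`
#' @export
sel_reference_cells <- function() {
  data.frame(
    range_km = c(1, 1, 3, 3, 6, 6, 12, 12),
    charge_lb = c(5, 20, 5, 20, 5, 20, 5, 20),
    sel_db = c(183, 187, 177, 181, 173, 177, 169, 173),
    peak_pa = c(39139, 65976, 11310, 19065, 5168, 8711, 2361, 3980)
  )
}

#' Calibrate the additive SEL constant
#'
#' The SEL similitude relation is
#' `SEL = 6.14 log10(W) - 13.26 log10(r) + A` with W the charge weight and
#' r the range in metres. A is fitted once by least squares to the
#' reference cells (a single intercept, so the fit is the mean residual)
#' rather than hard-coded, insulating the module against transcription
#' differences in the published constant.
#'
#' @param cells reference table, default [sel_reference_cells()]
#' @return the constant A (dB)
#' @export
calibrate_sel_constant <- function(cells = sel_reference_cells()) {
  mean(cells$sel_db - 6.14 * log10(cells$charge_lb) +
         13.26 * log10(cells$range_km * 1000))
}

#' Sound exposure level of a shallow-water detonation
#'
#' SEL (dB re 1 uPa^2 s) from the similitude relation
#' `6.14 log10(W) - 13.26 log10(r) + A`; increases with charge weight,
#' decreases with range.
#'
#' @param weight charge weight (> 0), as-printed nominal value (see
#'   [sel_reference_cells()])
#' @param range_m range in metres (> 0)
#' @param constant additive constant A; calibrated from the reference
#'   cells when omitted
#' @return SEL in dB (not rounded; round to the nearest dB for reporting)
#' @export
sel_db <- function(weight, range_m, constant = calibrate_sel_constant()) {
  if (any(weight <= 0) || any(range_m <= 0))
    stop("parameter error: weight and range must be > 0")
  6.14 * log10(weight) - 13.26 * log10(range_m) + constant
}

#' Peak pressure of a shallow-water detonation
#'
#' Similitude form `p = 52.16e6 * (W^(1/3) / r)^1.13` Pa with W the
#' as-printed charge weight and r the range in metres.
#'
#' @inheritParams sel_db
#' @return peak pressure in Pa
#' @export
peak_pressure <- function(weight, range_m) {
  if (any(weight <= 0) || any(range_m <= 0))
    stop("parameter error: weight and range must be > 0")
  52.16e6 * (weight^(1 / 3) / range_m)^1.13
}

#' Convert a nominal C4 charge weight to kg of TNT equivalent
#'
#' For physically explicit use of the similitude formulas: pounds of C4 to
#' kilograms of TNT equivalent (C4 carries ~1.34 times the energy of TNT
#' by mass).
#'
#' @param lb_c4 pounds of C4
#' @param equivalence TNT equivalence factor for C4
#' @return kg TNT
#' @export
lb_c4_to_kg_tnt <- function(lb_c4, equivalence = 1.34) {
  lb_c4 * 0.45359237 * equivalence
}

#' Exposure table for a set of charge scenarios
#'
#' @param weights charge weights
#' @param ranges_km ranges in km
#' @param constant SEL calibration constant
#' @return data.frame with one row per (range, weight) combination:
#'   `range_km`, `charge_lb`, `sel_db` (rounded to nearest dB),
#'   `peak_pa`
#' @export
exposure_table <- function(weights = c(5, 20), ranges_km = c(1, 3, 6, 12),
                           constant = calibrate_sel_constant()) {
  g <- expand.grid(charge_lb = weights, range_km = ranges_km)
  data.frame(range_km = g$range_km, charge_lb = g$charge_lb,
             sel_db = round(sel_db(g$charge_lb, g$range_km * 1000, constant)),
             peak_pa = peak_pressure(g$charge_lb, g$range_km * 1000))
}
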