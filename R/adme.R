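#' Tissue-to-plasma concentration ratio
#'
#' T/P ratio from a homogenate measurement and its paired plasma
#' concentration. Tissues are homogenized with added water, so the
#' measured homogenate concentration is multiplied by the dilution factor
#' (default 5: one part tissue plus four volumes of water) before taking
#' the ratio. Ratios above 1 are tagged as high-affinity tissues.
#'
#' @param tissue_conc homogenate concentration, ug/mL.
#' @param plasma_conc paired plasma concentration, ug/mL (> 0).
#' @param dilution_factor homogenate dilution (>= 1; default 5).
#' @return Numeric vector of T/P ratios with a logical
#'   `high_affinity` attribute (`ratio > 1`).
#' @export
#' @examples
#' tissue_to_plasma(2.0, 1.0, dilution_factor = 1)
tissue_to_plasma <- function(tissue_conc, plasma_conc, dilution_factor = 5) {
  if (any(plasma_conc <= 0)) {
    abort_adme("paired plasma concentration must be > 0",
               "admekit_zero_plasma")
  }
  if (any(tissue_conc < 0)) {
    abort_adme("tissue concentration must be >= 0", "admekit_negative_conc")
  }
  if (any(dilution_factor < 1)) {
    abort_adme("`dilution_factor` must be >= 1", "admekit_bad_dilution")
  }
  ratio <- tissue_conc * dilution_factor / plasma_conc
  attr(ratio, "high_affinity") <- ratio > 1
  ratio
}

#' Plasma protein binding from an equilibrium-dialysis pair
#'
#' At equilibrium only unbound drug crosses the membrane, so the
#' buffer-side concentration measures the free fraction:
#' `fu = buffer / plasma` and `bound% = 100 * (plasma - buffer) / plasma`.
#' Buffer-side concentrations above the plasma side are physically
#' impossible and are flagged (not rejected).
#'
#' @param plasma_side_conc plasma-side concentration, ug/mL (> 0).
#' @param buffer_side_conc buffer-side concentration, ug/mL (>= 0).
#' @return Tibble with columns `bound_pct`, `fu`, `flagged` (buffer above
#'   plasma).
#' @export
#' @examples
#' protein_binding(1.0, 0.082)  # 91.8% bound
protein_binding <- function(plasma_side_conc, buffer_side_conc) {
  if (any(plasma_side_conc <= 0)) {
    abort_adme("plasma-side concentration must be > 0",
               "admekit_zero_plasma")
  }
  if (any(buffer_side_conc < 0)) {
    abort_adme("buffer-side concentration must be >= 0",
               "admekit_negative_conc")
  }
  flagged <- buffer_side_conc > plasma_side_conc
  if (any(flagged)) {
    warn_adme("buffer-side concentration exceeds plasma side in some pairs",
              "admekit_binding_flag")
  }
  fu <- buffer_side_conc / plasma_side_conc
  tibble::tibble(bound_pct = 100 * (1 - fu), fu = fu, flagged = flagged)
}

#' Unbound renal clearance
#'
#' Renal clearance referenced to the unbound plasma concentration,
#' `CL_R,fu = CL_R / fu`. Compared against the mouse glomerular
#' filtration rate (default reference 14.0 mL/min/kg): values below GFR
#' are consistent with net filtration (with reabsorption), values above
#' imply tubular secretion.
#'
#' @param cl_r renal clearance, mL/min/kg (>= 0).
#' @param fu unbound fraction in (0, 1].
#' @param gfr_ml_min_kg reference glomerular filtration rate.
#' @return Numeric vector of unbound renal clearances with a character
#'   `gfr_comparison` attribute (`"below_gfr"`/`"above_gfr"`).
#' @export
#' @examples
#' unbound_renal_clearance(0.141, 1 - 0.918)  # 1.72
unbound_renal_clearance <- function(cl_r, fu, gfr_ml_min_kg = 14.0) {
  if (any(fu <= 0) || any(fu > 1)) {
    abort_adme("`fu` must lie in (0, 1]", "admekit_bad_fu")
  }
  if (any(cl_r < 0)) abort_adme("`cl_r` must be >= 0", "admekit_bad_clr")
  out <- cl_r / fu
  attr(out, "gfr_comparison") <- ifelse(out <= gfr_ml_min_kg,
                                        "below_gfr", "above_gfr")
  out
}

#' Fraction of an oral dose unabsorbed
#'
#' Corrects the 24-h gastrointestinal recovery after an oral dose for the
#' drug that re-entered the gut after absorption (biliary/intestinal
#' secretion), estimated from the recovery after an intravenous dose
#' scaled by the absorbed (bioavailable) fraction. The default
#' subtractive form is `F_unabs = GI24_oral - F * GI24_iv`; the
#' normalized variant additionally divides by `(1 - F)`. Results outside
#' \[0, 1\] are flagged with a warning, not rejected.
#'
#' @param gi24_oral_frac GI-tract recovery at 24 h after the oral dose,
#'   as a fraction of dose in \[0, 1\].
#' @param gi24_iv_frac GI-tract recovery at 24 h after the intravenous
#'   dose, fraction of dose.
#' @param f_frac absolute bioavailability as a fraction.
#' @param method `"subtractive"` (default) or `"normalized"`.
#' @return Fraction of the oral dose never absorbed.
#' @export
#' @examples
#' fraction_unabsorbed(0.435, 0.0228, 0.0229)  # ~0.434
fraction_unabsorbed <- function(gi24_oral_frac, gi24_iv_frac, f_frac,
                                method = c("subtractive", "normalized")) {
  method <- match.arg(method)
  args <- c(gi24_oral_frac, gi24_iv_frac, f_frac)
  if (any(args < 0) || any(args > 1)) {
    abort_adme("all inputs must be fractions in [0, 1]",
               "admekit_bad_fraction")
  }
  out <- gi24_oral_frac - f_frac * gi24_iv_frac
  if (method == "normalized") out <- out / (1 - f_frac)
  if (any(out < 0) || any(out > 1)) {
    warn_adme("fraction unabsorbed outside [0, 1]",
              "admekit_funabs_out_of_range")
  }
  out
}

#' S9 metabolic disappearance
#'
#' Percent of the spiked parent concentration lost over an S9 incubation,
#' `100 * (1 - remaining / spiked)`. Apparent negative disappearance
#' (remaining above spiked, i.e. assay noise) is clipped to 0 with a
#' warning.
#'
#' @param spiked_conc spiked concentration, ug/mL (> 0).
#' @param remaining_conc remaining concentration after incubation, ug/mL
#'   (>= 0).
#' @return Disappearance in percent, in \[0, 100\].
#' @export
#' @examples
#' s9_disappearance(1.0, 0.427)  # 57.3
s9_disappearance <- function(spiked_conc, remaining_conc) {
  if (any(spiked_conc <= 0)) {
    abort_adme("`spiked_conc` must be > 0", "admekit_bad_conc")
  }
  if (any(remaining_conc < 0)) {
    abort_adme("`remaining_conc` must be >= 0", "admekit_negative_conc")
  }
  out <- 100 * (1 - remaining_conc / spiked_conc)
  if (any(out < 0)) {
    warn_adme("remaining concentration exceeds spiked; clipping disappearance to 0",
              "admekit_negative_disappearance")
    out <- pmax(out, 0)
  }
  out
}

#' S9 disappearance summary table
#'
#' Per-tissue, per-concentration disappearance summary of a set of S9
#' incubations (the layout of a tissue-panel stability figure).
#'
#' @param s9 tibble from [simulate_s9()] or equivalent, with columns
#'   `tissue`, `spiked_conc`, `remaining_conc`.
#' @return Tibble: `tissue`, `spiked_conc`, `disappearance_pct`.
#' @export
s9_summary <- function(s9) {
  dplyr::mutate(s9[, c("tissue", "spiked_conc")],
                disappearance_pct = s9_disappearance(s9$spiked_conc,
                                                     s9$remaining_conc))
}

#' Percent of dose excreted
#'
#' @param amount_excreted_ug amount recovered, ug (>= 0).
#' @param dose_amount_ug administered amount, ug (> 0).
#' @return Percent of dose.
#' @export
#' @examples
#' excretion_percent(41.95, 5000)  # 0.839
excretion_percent <- function(amount_excreted_ug, dose_amount_ug) {
  if (any(dose_amount_ug <= 0)) {
    abort_adme("`dose_amount_ug` must be > 0", "admekit_bad_dose")
  }
  if (any(amount_excreted_ug < 0)) {
    abort_adme("`amount_excreted_ug` must be >= 0",
               "admekit_negative_excretion")
  }
  100 * amount_excreted_ug / dose_amount_ug
}
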