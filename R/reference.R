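#' Published mouse pharmacokinetic summary for alpha-mangostin
#'
#' Group-level pharmacokinetic and excretion parameters (mean and SD;
#' median and range for Tmax) for alpha-mangostin in ICR mice after
#' intravenous bolus (5, 10, 20 mg/kg) and oral (10, 50, 100 mg/kg)
#' administration, as transcribed from the published study that calibrates
#' this package. These group summaries are inputs to the derived-metric
#' functions (bioavailability, clearance partition, unbound renal
#' clearance, fraction unabsorbed) and to the simulator defaults; the
#' underlying per-animal concentration data were never deposited.
#'
#' @return A tibble with columns `route` ("iv_bolus"/"oral"), `dose_mg_kg`,
#'   `n`, `parameter`, `mean`, `sd` (`NA` for Tmax, which is reported as
#'   `median` with `range_lo`/`range_hi`), and `units`.
#' @export
#' @examples
#' amg_pk_reference()
amg_pk_reference <- function() {
  row <- function(route, dose, n, parameter, mean, sd, units,
                  median = NA_real_, lo = NA_real_, hi = NA_real_) {
    tibble::tibble(route = route, dose_mg_kg = dose, n = n,
                   parameter = parameter, mean = mean, sd = sd,
                   median = median, range_lo = lo, range_hi = hi,
                   units = units)
  }
  iv <- function(dose, n, parameter, mean, sd, units)
    row("iv_bolus", dose, n, parameter, mean, sd, units)
  po <- function(dose, n, parameter, mean, sd, units)
    row("oral", dose, n, parameter, mean, sd, units)
  dplyr::bind_rows(
    iv(5, 9,  "body_weight",    30.9, 5.67,  "g"),
    iv(10, 8, "body_weight",    36.4, 6.87,  "g"),
    iv(20, 8, "body_weight",    33.3, 3.46,  "g"),
    iv(5, 9,  "auc",            169,  42.7,  "ug.min/mL"),
    iv(10, 8, "auc",            340,  99.4,  "ug.min/mL"),
    iv(20, 8, "auc",            633,  226,   "ug.min/mL"),
    iv(5, 9,  "auc_norm",       33.8, 8.53,  "ug.min/mL per mg/kg"),
    iv(10, 8, "auc_norm",       32.1, 8.91,  "ug.min/mL per mg/kg"),
    iv(20, 8, "auc_norm",       31.7, 11.3,  "ug.min/mL per mg/kg"),
    iv(5, 9,  "t_half",         226,  34.3,  "min"),
    iv(10, 8, "t_half",         219,  73.8,  "min"),
    iv(20, 8, "t_half",         173,  71.9,  "min"),
    iv(5, 9,  "mrt",            145,  27.7,  "min"),
    iv(10, 8, "mrt",            160,  67.0,  "min"),
    iv(20, 8, "mrt",            144,  68.5,  "min"),
    iv(5, 9,  "cl",             31.4, 7.28,  "mL/min/kg"),
    iv(10, 8, "cl",             31.3, 7.95,  "mL/min/kg"),
    iv(20, 8, "cl",             34.7, 12.4,  "mL/min/kg"),
    iv(5, 9,  "cl_r",           0.283, 0.194, "mL/min/kg"),
    iv(10, 8, "cl_r",           0.205, 0.150, "mL/min/kg"),
    iv(20, 8, "cl_r",           0.141, 0.0801, "mL/min/kg"),
    iv(5, 9,  "cl_nr",          31.1, 7.14,  "mL/min/kg"),
    iv(10, 8, "cl_nr",          31.1, 7.83,  "mL/min/kg"),
    iv(20, 8, "cl_nr",          34.6, 12.3,  "mL/min/kg"),
    iv(5, 9,  "vss",            4304, 1005,  "mL/kg"),
    iv(10, 8, "vss",            4270, 1974,  "mL/kg"),
    iv(20, 8, "vss",            4500, 1381,  "mL/kg"),
    iv(5, 9,  "ae_0_24",        0.839, 0.525, "% of dose"),
    iv(10, 8, "ae_0_24",        0.592, 0.394, "% of dose"),
    iv(20, 8, "ae_0_24",        0.403, 0.163, "% of dose"),
    iv(5, 9,  "gi_24",          3.44, 1.16,  "% of dose"),
    iv(10, 8, "gi_24",          2.28, 1.96,  "% of dose"),
    iv(20, 8, "gi_24",          3.42, 1.73,  "% of dose"),
    po(10, 8,  "body_weight",   25.0, 0.310, "g"),
    po(50, 7,  "body_weight",   25.3, 1.89,  "g"),
    po(100, 9, "body_weight",   27.9, 3.62,  "g"),
    po(10, 8,  "auc",           7.80, 2.58,  "ug.min/mL"),
    po(50, 7,  "auc",           37.3, 10.5,  "ug.min/mL"),
    po(100, 9, "auc",           83.2, 23.8,  "ug.min/mL"),
    po(10, 8,  "auc_norm",      0.861, 0.258, "ug.min/mL per mg/kg"),
    po(50, 7,  "auc_norm",      0.746, 0.209, "ug.min/mL per mg/kg"),
    po(100, 9, "auc_norm",      0.831, 0.274, "ug.min/mL per mg/kg"),
    po(10, 8,  "t_half",        177,  71.1,  "min"),
    po(50, 7,  "t_half",        197,  81.0,  "min"),
    po(100, 9, "t_half",        151,  49.3,  "min"),
    po(10, 8,  "cmax",          0.0403, 0.0307, "ug/mL"),
    po(50, 7,  "cmax",          0.242, 0.0350, "ug/mL"),
    po(100, 9, "cmax",          0.709, 0.397, "ug/mL"),
    po(10, 8,  "cmax_norm",     0.00403, 0.00306, "ug/mL per mg/kg"),
    po(50, 7,  "cmax_norm",     0.00484, 0.000698, "ug/mL per mg/kg"),
    po(100, 9, "cmax_norm",     0.00708, 0.00396, "ug/mL per mg/kg"),
    row("oral", 10, 8,  "tmax", NA, NA, "min", median = 60, lo = 15, hi = 120),
    row("oral", 50, 7,  "tmax", NA, NA, "min", median = 30, lo = 15, hi = 60),
    row("oral", 100, 9, "tmax", NA, NA, "min", median = 60, lo = 15, hi = 360),
    po(10, 8,  "cl_r",          0.535, 0.309, "mL/min/kg"),
    po(50, 7,  "cl_r",          0.547, 0.309, "mL/min/kg"),
    po(100, 9, "cl_r",          0.418, 0.229, "mL/min/kg"),
    po(10, 8,  "ae_0_24",       0.0255, 0.0107, "% of dose"),
    po(50, 7,  "ae_0_24",       0.0315, 0.0241, "% of dose"),
    po(100, 9, "ae_0_24",       0.0270, 0.0113, "% of dose"),
    po(10, 8,  "gi_24",         43.5, 10.6,  "% of dose"),
    po(50, 7,  "gi_24",         40.2, 11.6,  "% of dose"),
    po(100, 9, "gi_24",         41.2, 4.51,  "% of dose")
  )
}

#' Published in-vitro ADME summary for alpha-mangostin
#'
#' Plasma protein binding (equilibrium dialysis, two spiked
#' concentrations), hepatic/intestinal S9 disappearance at 30 min, and the
#' mouse glomerular-filtration-rate reference used to contextualize
#' unbound renal clearance.
#'
#' @return A named list: `binding_pct` (tibble: spiked_conc_ug_ml, mean,
#'   sd), `s9_disappearance_pct` (tibble: tissue, spiked_conc_ug_ml,
#'   disappearance_pct), and `gfr_ml_min_kg` (scalar, 14.0).
#' @export
amg_invitro_reference <- function() {
  list(
    binding_pct = tibble::tibble(
      spiked_conc_ug_ml = c(1, 20),
      mean = c(91.8, 89.3),
      sd = c(13.5, 11.6)
    ),
    s9_disappearance_pct = tibble::tibble(
      tissue = c("liver", "small_intestine", "liver", "small_intestine"),
      spiked_conc_ug_ml = c(1, 1, 20, 20),
      disappearance_pct = c(57.3, 34.8, 51.4, 36.2)
    ),
    gfr_ml_min_kg = 14.0
  )
}

#' Published metabolite survey peak list for alpha-mangostin
#'
#' The centroided precursor/product-ion survey of alpha-mangostin and its
#' fifteen tentative metabolites observed in mouse plasma, urine, feces,
#' liver, small intestine and tissue S9 incubations, transcribed as a peak
#' list: protonated-molecule m/z, retention time on the survey gradient,
#' product-ion m/z values, and the matrices in which each peak was seen.
#' The `reaction` column carries the published biotransformation
#' assignment and is the reference annotation the annotator is tested
#' against; `annotate_peaklist()` does not read it.
#'
#' @return A tibble with columns `peak_id`, `precursor_mz`, `rt_min`,
#'   `fragments` (list of numeric), `sources` (list of character),
#'   `reaction`.
#' @export
#' @examples
#' amg_metabolite_peaks()
amg_metabolite_peaks <- function() {
  all6 <- c("plasma", "urine", "feces", "liver", "small_intestine",
            "S9_liver", "S9_intestine")
  ufli <- c("urine", "feces", "liver", "small_intestine")
  lif <- c("liver", "small_intestine", "feces")
  tibble::tibble(
    peak_id = c("parent", paste0("M", 1:15)),
    precursor_mz = c(411.21, 587.17, 587.04, 587.23, 763.21, 409.07,
                     409.07, 409.33, 409.14, 413.00, 427.17, 426.85,
                     427.30, 427.43, 426.98, 425.04),
    rt_min = c(27.6, 21.4, 25.1, 26.6, 21.0, 20.8, 24.7, 25.0, 27.6,
               26.6, 16.5, 18.2, 24.6, 26.4, 27.4, 28.2),
    fragments = list(
      c(354.85, 299.19),
      c(355.18, 104.30),
      c(531.18, 411.05, 354.86),
      c(530.98, 411.17, 354.86),
      c(707.15, 587.06, 530.99, 411.23, 355.10),
      c(352.91, 334.81, 289.04),
      c(353.23, 321.04, 83.98),
      c(353.10),
      c(352.91, 334.94),
      c(356.92),
      c(371.33, 354.85, 132.86, 105.25),
      c(354.97),
      c(408.94, 385.22, 354.91, 353.04, 272.95),
      c(371.13, 341.27, 299.26),
      c(408.94, 315.16),
      c(369.19, 351.10)
    ),
    sources = list(all6, all6, all6, all6,
                   c("plasma", "feces", "liver", "small_intestine"),
                   ufli, ufli, ufli, ufli, "urine",
                   lif, lif, lif, lif, lif, lif),
    reaction = c("parent", "glucuronidation", "glucuronidation",
                 "glucuronidation", "bis_glucuronidation",
                 "dehydrogenation", "dehydrogenation", "dehydrogenation",
                 "dehydrogenation", "hydrogenation", "oxidation",
                 "oxidation", "oxidation", "oxidation", "oxidation",
                 "methylation")
  )
}

#' Study sampling schedules
#'
#' The blood-sampling schedules of the calibrating mouse study: 0-360 min,
#' twelve points after an intravenous bolus and eleven after an oral dose.
#'
#' @param route `"iv_bolus"` or `"oral"`.
#' @return Numeric vector of sampling times in minutes.
#' @export
amg_schedule <- function(route = c("iv_bolus", "oral")) {
  route <- match.arg(route)
  switch(route,
    iv_bolus = c(0, 1, 5, 15, 30, 60, 90, 120, 180, 240, 300, 360),
    oral = c(0, 5, 15, 30, 60, 90, 120, 180, 240, 300, 360)
  )
}
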