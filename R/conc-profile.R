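#' Concentration-time profile for one subject
#'
#' The basic container consumed by the NCA functions: one subject's
#' concentration-time series in a single matrix (plasma, a named tissue, or
#' urine), with explicit below-LLOQ censoring. Censored observations keep
#' their row — the concentration is `NA` and the `censored` flag is set —
#' so that sampling design is never silently lost.
#'
#' @param subject_id identifier (coerced to character).
#' @param times sampling times in minutes; non-negative, strictly
#'   increasing.
#' @param conc concentrations in ug/mL; `NA` allowed only where `censored`
#'   is `TRUE`. Finite values below `lloq` are censored (set to `NA`,
#'   flagged) on construction.
#' @param lloq lower limit of quantitation in ug/mL.
#' @param matrix one of `"plasma"`, `"urine"`, or `"tissue:<name>"`.
#' @param route `"iv_bolus"` or `"oral"`, or `NA` when not a dosing matrix.
#' @param dose dose in mg/kg associated with the profile (optional,
#'   recorded for downstream NCA).
#' @param censored optional logical vector; inferred from `conc < lloq`
#'   when omitted.
#'
#' @return An object of class `conc_profile`: a list with elements
#'   `subject_id`, `matrix`, `route`, `dose`, `times`, `conc`, `censored`,
#'   `lloq`.
#' @export
#' @examples
#' conc_profile("m1", times = c(0, 30, 60), conc = c(1.2, 0.6, 0.3),
#'              lloq = 0.001)
conc_profile <- function(subject_id, times, conc, lloq,
                         matrix = "plasma", route = NA_character_,
                         dose = NA_real_, censored = NULL) {
  subject_id <- as.character(subject_id)
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  if (length(times) != length(conc)) {
    abort_adme("`times` and `conc` must have the same length",
               "admekit_length_mismatch")
  }
  if (any(times < 0)) {
    abort_adme("sampling times must be non-negative", "admekit_negative_time")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    abort_adme("sampling times must be strictly increasing",
               "admekit_nonmonotone_times")
  }
  if (any(conc < 0, na.rm = TRUE)) {
    abort_adme("concentrations must be non-negative", "admekit_negative_conc")
  }
  if (!is.numeric(lloq) || length(lloq) != 1L || lloq < 0) {
    abort_adme("`lloq` must be a single non-negative number",
               "admekit_bad_lloq")
  }
  if (is.null(censored)) censored <- rep(FALSE, length(conc))
  censored <- as.logical(censored) | (!is.na(conc) & conc < lloq)
  conc[censored] <- NA_real_
  if (any(is.na(conc) & !censored)) {
    abort_adme("missing concentrations must carry the censored flag",
               "admekit_na_conc")
  }
  route <- as.character(route)
  if (!is.na(route) && !route %in% c("iv_bolus", "oral")) {
    abort_adme("`route` must be \"iv_bolus\" or \"oral\"",
               "admekit_bad_route")
  }
  structure(
    list(subject_id = subject_id, matrix = matrix, route = route,
         dose = as.numeric(dose), times = times, conc = conc,
         censored = censored, lloq = lloq),
    class = "conc_profile"
  )
}

#' @export
print.conc_profile <- function(x, ...) {
  n_q <- sum(!x$censored)
  cat(sprintf("<conc_profile> subject %s, %s%s, %d points (%d quantifiable), LLOQ %g ug/mL\n",
              x$subject_id, x$matrix,
              if (!is.na(x$route)) paste0(", ", x$route, " ",
                                          format(x$dose), " mg/kg") else "",
              length(x$times), n_q, x$lloq))
  print(as_tibble(x))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
#' @importFrom tibble as_tibble
as_tibble.conc_profile <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id, matrix = x$matrix, route = x$route,
    dose_mg_kg = x$dose, time_min = x$times, conc_ug_ml = x$conc,
    censored = x$censored, lloq_ug_ml = x$lloq
  )
}

# Quantifiable (non-censored) points of a profile, as a two-column matrix.
quantifiable_points <- function(profile) {
  keep <- !profile$censored
  list(times = profile$times[keep], conc = profile$conc[keep])
}

#' Excretion record for one subject
#'
#' Urinary and gastrointestinal recoveries of unchanged drug over 24 h,
#' expressed as percent of dose.
#'
#' @param subject_id identifier.
#' @param ae_0_24_pct percent of dose excreted unchanged in urine over
#'   0-24 h.
#' @param gi_24_pct percent of dose recovered unchanged in the GI tract
#'   (contents plus feces) at 24 h.
#' @param urine_amount_ug total amount in urine (ug), optional.
#' @return A one-row tibble of class `excretion_record`.
#' @export
excretion_record <- function(subject_id, ae_0_24_pct, gi_24_pct,
                             urine_amount_ug = NA_real_) {
  if (any(c(ae_0_24_pct, gi_24_pct) < 0, na.rm = TRUE)) {
    abort_adme("excretion percentages must be non-negative",
               "admekit_negative_excretion")
  }
  out <- tibble::tibble(subject_id = as.character(subject_id),
                        ae_0_24_pct = as.numeric(ae_0_24_pct),
                        gi_24_pct = as.numeric(gi_24_pct),
                        urine_amount_ug = as.numeric(urine_amount_ug))
  class(out) <- c("excretion_record", class(out))
  out
}
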