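#' Match one precursor peak against the biotransformation rules
#'
#' Computes the observed mass shift of a precursor from the parent and
#' ranks every rule whose monoisotopic shift lies within the tolerance.
#' A peak within tolerance of the parent m/z itself is assigned
#' `"parent"`; a peak matching no rule is `"unassigned"` (a valid
#' outcome, not an error). Ties — several rules within tolerance — are
#' all returned, ranked by absolute mass error, never silently dropped.
#'
#' @param precursor_mz observed precursor m/z, Da.
#' @param parent a [parent_spec()].
#' @param rules rule table from [build_rule_table()].
#' @param tolerance_da precursor mass tolerance, Da (> 0). Default 0.5 Da,
#'   appropriate for unit-resolution triple-quadrupole data.
#' @return Tibble of candidate assignments, best first: `rule`,
#'   `observed_shift`, `mass_error`, `nominal_shift`.
#' @export
#' @examples
#' match_peak(587.17)
match_peak <- function(precursor_mz, parent = parent_spec(),
                       rules = build_rule_table(), tolerance_da = 0.5) {
  if (tolerance_da <= 0) abort_adme("`tolerance_da` must be > 0",
                                    "admekit_bad_tolerance")
  shift <- precursor_mz - parent$parent_mz
  if (abs(shift) <= tolerance_da) {
    return(tibble::tibble(rule = "parent", observed_shift = shift,
                          mass_error = shift, nominal_shift = 0))
  }
  err <- shift - rules$mono_shift
  hit <- abs(err) <= tolerance_da
  if (!any(hit)) {
    return(tibble::tibble(rule = "unassigned", observed_shift = shift,
                          mass_error = NA_real_,
                          nominal_shift = round(shift)))
  }
  out <- tibble::tibble(rule = rules$name[hit], observed_shift = shift,
                        mass_error = err[hit],
                        nominal_shift = round(shift))
  out[order(abs(out$mass_error)), ]
}

#' Count diagnostic fragment evidence for an assignment
#'
#' Compares a peak's observed product ions with the neutral-loss
#' templates of its assigned rule: every class is expected to lose the
#' prenyl unit (once or twice); glucuronides additionally lose the
#' glycone(s) and show the aglycone-minus-prenyl cascade. Each observed
#' fragment is counted at most once, against its nearest template within
#' tolerance.
#'
#' @param fragments numeric vector of observed product-ion m/z, Da (may
#'   be empty).
#' @param precursor_mz observed precursor m/z, Da.
#' @param rule assigned rule name (`"parent"` or a
#'   [build_rule_table()] name); `"unassigned"` yields 0.
#' @param parent a [parent_spec()].
#' @param tolerance_da fragment mass tolerance, Da.
#' @return Integer count of matched diagnostic fragments.
#' @export
#' @examples
#' fragment_evidence(c(354.85, 299.19), 411.21, "parent")
fragment_evidence <- function(fragments, precursor_mz, rule,
                              parent = parent_spec(), tolerance_da = 0.5) {
  if (length(fragments) == 0L || rule == "unassigned") return(0L)
  templates <- fragment_templates(rule, precursor_mz, parent)
  sum(vapply(fragments, function(f) any(abs(f - templates) <= tolerance_da),
             logical(1)))
}

#' Retention-time polarity consistency of an assignment
#'
#' Phase I/II metabolites are more polar than the parent and elute
#' earlier on reversed phase — except methylated metabolites, whose
#' reduced hydrophilicity shifts them later. The check is a reported
#' flag, never a hard filter; co-elution with the parent counts as
#' consistent for "earlier" rules.
#'
#' @param peak_rt observed retention time, min.
#' @param parent a [parent_spec()].
#' @param rule rule name; `"parent"` and `"unassigned"` return `NA`.
#' @param rules rule table from [build_rule_table()].
#' @return Logical flag (or `NA` when no direction applies).
#' @export
rt_consistency <- function(peak_rt, parent = parent_spec(), rule,
                           rules = build_rule_table()) {
  if (rule %in% c("parent", "unassigned")) return(NA)
  dir <- rules$rt_direction[match(rule, rules$name)]
  if (is.na(dir)) abort_adme(sprintf("unknown rule \"%s\"", rule),
                             "admekit_unknown_rule")
  if (dir == "earlier") peak_rt <= parent$parent_rt
  else peak_rt > parent$parent_rt
}

#' Annotate a peak list with tentative metabolite assignments
#'
#' Runs the full tentative-identification chain over a peak list: each
#' precursor is matched against the biotransformation mass-shift rules,
#' its diagnostic fragment evidence is counted, and its retention-time
#' polarity is flagged against the parent. One row per peak (the best
#' assignment; ties are noted in `n_candidates`), ordered
#' deterministically by retention time then m/z.
#'
#' @param peaks peak-list tibble with columns `peak_id`, `precursor_mz`,
#'   `rt_min`, and optionally `fragments` (list of numeric) and `sources`
#'   (list of character). Duplicate `peak_id`s are rejected.
#' @param parent a [parent_spec()].
#' @param rules rule table from [build_rule_table()].
#' @param tolerance_da precursor and fragment mass tolerance, Da.
#' @return Tibble: `peak_id`, `precursor_mz`, `rt_min`, `rule`,
#'   `observed_shift`, `mass_error_da`, `nominal_shift_da`,
#'   `fragment_evidence`, `rt_consistent`, `n_candidates`, `sources`.
#' @export
#' @examples
#' annotate_peaklist(amg_metabolite_peaks())
annotate_peaklist <- function(peaks, parent = parent_spec(),
                              rules = build_rule_table(),
                              tolerance_da = 0.5) {
  required <- c("peak_id", "precursor_mz", "rt_min")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    abort_adme(paste0("peak list lacks column(s): ",
                      paste(missing, collapse = ", ")),
               "admekit_missing_column")
  }
  if (anyDuplicated(peaks$peak_id)) {
    abort_adme("duplicate peak_ids in peak list", "admekit_duplicate_peak")
  }
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(peak_id = character(), precursor_mz = numeric(),
                          rt_min = numeric(), rule = character(),
                          observed_shift = numeric(),
                          mass_error_da = numeric(),
                          nominal_shift_da = numeric(),
                          fragment_evidence = integer(),
                          rt_consistent = logical(),
                          n_candidates = integer(), sources = list()))
  }
  frags <- if ("fragments" %in% names(peaks)) peaks$fragments
           else rep(list(numeric()), nrow(peaks))
  srcs <- if ("sources" %in% names(peaks)) peaks$sources
          else rep(list(character()), nrow(peaks))
  bad_frag <- vapply(seq_len(nrow(peaks)), function(i) {
    any(frags[[i]] >= peaks$precursor_mz[i] + tolerance_da)
  }, logical(1))
  if (any(bad_frag)) {
    warn_adme("some product ions exceed their precursor m/z",
              "admekit_fragment_above_precursor")
  }
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- match_peak(peaks$precursor_mz[i], parent, rules, tolerance_da)
    best <- cand[1, ]
    tibble::tibble(
      peak_id = peaks$peak_id[i],
      precursor_mz = peaks$precursor_mz[i],
      rt_min = peaks$rt_min[i],
      rule = best$rule,
      observed_shift = best$observed_shift,
      mass_error_da = best$mass_error,
      nominal_shift_da = best$nominal_shift,
      fragment_evidence = fragment_evidence(frags[[i]],
                                            peaks$precursor_mz[i],
                                            best$rule, parent,
                                            tolerance_da),
      rt_consistent = rt_consistency(peaks$rt_min[i], parent, best$rule,
                                     rules),
      n_candidates = if (best$rule %in% c("parent", "unassigned")) 1L
                     else nrow(cand),
      sources = list(srcs[[i]])
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$rt_min, out$precursor_mz), ]
}
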