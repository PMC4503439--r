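#' Simulate equilibrium-dialysis pairs
#'
#' Emulates an equilibrium dialysis experiment: drug spiked into the
#' plasma compartment equilibrates so that the buffer-side concentration
#' is the unbound fraction `fu_true` times the plasma-side concentration,
#' plus proportional measurement noise. Pairs are strictly positive.
#'
#' @param fu_true true unbound fraction in (0, 1].
#' @param spiked_conc initial plasma-side concentration, ug/mL.
#' @param noise_sd proportional measurement-noise SD applied to both
#'   sides (0 disables).
#' @param n number of replicate dialysis cells.
#' @param seed optional integer seed.
#' @return Tibble with columns `plasma_side_conc`, `buffer_side_conc`,
#'   `spiked_conc`.
#' @export
#' @examples
#' simulate_dialysis(fu_true = 0.082, spiked_conc = 1, noise_sd = 0, n = 1)
simulate_dialysis <- function(fu_true, spiked_conc = 1, noise_sd = 0,
                              n = 6, seed = NULL) {
  if (!is.numeric(fu_true) || fu_true <= 0 || fu_true > 1) {
    abort_adme("`fu_true` must lie in (0, 1]", "admekit_bad_fu")
  }
  if (spiked_conc <= 0) abort_adme("`spiked_conc` must be > 0",
                                   "admekit_bad_conc")
  if (!is.null(seed)) set.seed(seed)
  jitter <- function(x) {
    if (noise_sd == 0) return(x)
    pmax(x * (1 + rnorm(n, 0, noise_sd)), .Machine$double.eps)
  }
  plasma <- jitter(rep(spiked_conc, n))
  buffer <- jitter(fu_true * plasma)
  tibble::tibble(plasma_side_conc = plasma, buffer_side_conc = buffer,
                 spiked_conc = spiked_conc)
}

#' Simulate S9 metabolic-stability incubations
#'
#' Emulates a 30-min tissue S9 incubation: the remaining parent
#' concentration follows first-order depletion,
#' `remaining = spiked * exp(-kdep * t_inc) * (1 + noise)`. Tissues with
#' `kdep = 0` return the spiked concentration unchanged (no metabolic
#' activity).
#'
#' @param kdep named numeric vector of first-order depletion rate
#'   constants per tissue, 1/min (>= 0).
#' @param t_inc incubation time, min (default 30).
#' @param spiked_conc spiked concentration, ug/mL.
#' @param noise_sd proportional noise SD on the remaining concentration.
#' @param seed optional integer seed.
#' @return Tibble with columns `tissue`, `spiked_conc`, `remaining_conc`.
#' @export
#' @examples
#' simulate_s9(c(liver = 0.01, brain = 0), spiked_conc = 1)
simulate_s9 <- function(kdep, t_inc = 30, spiked_conc = 1, noise_sd = 0,
                        seed = NULL) {
  if (any(kdep < 0)) abort_adme("`kdep` must be >= 0", "admekit_bad_kdep")
  if (spiked_conc <= 0) abort_adme("`spiked_conc` must be > 0",
                                   "admekit_bad_conc")
  if (!is.null(seed)) set.seed(seed)
  tissue <- names(kdep) %||% paste0("tissue_", seq_along(kdep))
  remaining <- spiked_conc * exp(-kdep * t_inc)
  if (noise_sd > 0) {
    remaining <- pmax(remaining * (1 + rnorm(length(kdep), 0, noise_sd)), 0)
  }
  tibble::tibble(tissue = tissue, spiked_conc = spiked_conc,
                 remaining_conc = unname(remaining))
}

#' Specification for synthetic MS peak lists
#'
#' Describes how to fabricate a centroided precursor/product-ion peak list
#' from a parent mass and a set of biotransformation rules, for round-trip
#' testing of the annotator. Retention times mimic the observed
#' chromatographic behaviour: every metabolite class elutes earlier than
#' the parent except methylation, which elutes later (reduced
#' hydrophilicity). Class offsets are drawn uniformly in \[-12, -1\] min
#' (earlier classes) or \[+0.3, +1\] min (methylation).
#'
#' @param parent_mz protonated-molecule m/z of the parent, Da.
#' @param parent_rt parent retention time, min.
#' @param reactions character vector of rule names from
#'   [build_rule_table()] to apply (possibly empty).
#' @param mz_noise_sd additive m/z noise SD, Da (>= 0).
#' @param seed optional integer seed.
#' @return A list of class `peaklist_spec`.
#' @export
peaklist_spec <- function(parent_mz = 411.21, parent_rt = 27.6,
                          reactions = character(), mz_noise_sd = 0,
                          seed = NULL) {
  if (parent_mz <= 0) abort_adme("`parent_mz` must be > 0",
                                 "admekit_bad_mz")
  if (mz_noise_sd < 0) abort_adme("`mz_noise_sd` must be >= 0",
                                  "admekit_bad_mz")
  structure(list(parent_mz = parent_mz, parent_rt = parent_rt,
                 reactions = as.character(reactions),
                 mz_noise_sd = mz_noise_sd, seed = seed),
            class = "peaklist_spec")
}

#' Simulate a metabolite peak list
#'
#' Generates one peak per requested biotransformation at
#' `parent_mz + mono_shift + noise`, alongside the parent peak. Each peak
#' carries the diagnostic product ions of its rule (prenyl and, for
#' glucuronides, glycone neutral losses), and a retention time consistent
#' with the rule's polarity direction.
#'
#' @param spec a [peaklist_spec()].
#' @param rules rule table from [build_rule_table()].
#' @return Peak-list tibble with columns `peak_id`, `precursor_mz`,
#'   `rt_min`, `fragments` (list of numeric), `sources` (list of
#'   character).
#' @export
#' @examples
#' simulate_peaklist(peaklist_spec(reactions = "glucuronidation"))
simulate_peaklist <- function(spec, rules = build_rule_table()) {
  if (!inherits(spec, "peaklist_spec")) {
    abort_adme("`spec` must be a peaklist_spec", "admekit_bad_spec")
  }
  unknown <- setdiff(spec$reactions, rules$name)
  if (length(unknown)) {
    abort_adme(paste0("unknown reaction(s): ", paste(unknown, collapse = ", ")),
               "admekit_unknown_rule")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  noise <- function(k) if (spec$mz_noise_sd > 0) rnorm(k, 0, spec$mz_noise_sd) else rep(0, k)
  parent_frags <- fragment_templates("parent", spec$parent_mz)
  rows <- list(tibble::tibble(
    peak_id = "parent",
    precursor_mz = spec$parent_mz + noise(1),
    rt_min = spec$parent_rt,
    fragments = list(parent_frags + noise(length(parent_frags))),
    sources = list("synthetic")
  ))
  for (i in seq_along(spec$reactions)) {
    rule <- rules[rules$name == spec$reactions[i], ]
    mz <- spec$parent_mz + rule$mono_shift + noise(1)
    rt_off <- if (rule$rt_direction == "later") runif(1, 0.3, 1) else runif(1, -12, -1)
    frags <- fragment_templates(rule$name, mz)
    rows[[i + 1L]] <- tibble::tibble(
      peak_id = sprintf("S%02d_%s", i, rule$name),
      precursor_mz = mz,
      rt_min = spec$parent_rt + rt_off,
      fragments = list(frags + noise(length(frags))),
      sources = list("synthetic")
    )
  }
  dplyr::bind_rows(rows)
}
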