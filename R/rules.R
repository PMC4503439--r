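# Monoisotopic atomic masses (Da), CODATA/IUPAC values to enough digits
# that rule shifts are exact to < 1e-4 Da.
MONOISOTOPIC_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

#' Monoisotopic mass of an elemental composition change
#'
#' Parses a signed elemental formula such as `"+C6H8O6"`, `"-H2"` or
#' `"+O"` and returns its monoisotopic mass in Da, negative for losses.
#'
#' @param formula character scalar; an optional leading `+`/`-` sign
#'   followed by element symbols with optional counts.
#' @return Signed monoisotopic mass (Da).
#' @export
#' @examples
#' formula_mono_mass("+CH2")   # methylation shift
#' formula_mono_mass("-H2")    # dehydrogenation shift
formula_mono_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  sign <- 1
  body <- formula
  if (grepl("^[+-]", body)) {
    if (substr(body, 1, 1) == "-") sign <- -1
    body <- substr(body, 2, nchar(body))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  parts <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  if (!nzchar(body) || paste(parts, collapse = "") != body) {
    abort_adme(sprintf("cannot parse formula \"%s\"", formula),
               "admekit_bad_formula")
  }
  total <- 0
  for (p in parts) {
    el <- gsub("[0-9]+$", "", p)
    nct <- sub("^[A-Za-z]+", "", p)
    count <- if (nzchar(nct)) as.integer(nct) else 1L
    if (!el %in% names(MONOISOTOPIC_MASS)) {
      abort_adme(sprintf("element \"%s\" not in the atomic-mass table", el),
                 "admekit_unknown_element")
    }
    total <- total + MONOISOTOPIC_MASS[[el]] * count
  }
  sign * total
}

# Diagnostic neutral-loss unit: the prenyl side chain C4H8.
PRENYL_MASS <- 4 * 12 + 8 * 1.0078250319  # 56.0626 Da

#' Biotransformation rule table
#'
#' The six biotransformation classes used for tentative metabolite
#' identification, with their elemental composition changes and
#' monoisotopic mass shifts recomputed from the atomic-mass table at call
#' time (never hard-coded literals). Every class elutes earlier than the
#' parent on reversed phase (increased polarity) except methylation,
#' which elutes later.
#'
#' @return A tibble with columns `name`, `formula_delta`, `mono_shift`
#'   (Da), `nominal_shift` (rounded Da), `phase` ("I"/"II"),
#'   `rt_direction` ("earlier"/"later").
#' @export
#' @examples
#' build_rule_table()
build_rule_table <- function() {
  rules <- tibble::tibble(
    name = c("glucuronidation", "bis_glucuronidation", "dehydrogenation",
             "hydrogenation", "oxidation", "methylation"),
    formula_delta = c("+C6H8O6", "+C12H16O12", "-H2", "+H2", "+O", "+CH2"),
    phase = c("II", "II", "I", "I", "I", "I"),
    rt_direction = c("earlier", "earlier", "earlier", "earlier",
                     "earlier", "later")
  )
  rules$mono_shift <- vapply(rules$formula_delta, formula_mono_mass,
                             numeric(1), USE.NAMES = FALSE)
  rules$nominal_shift <- round(rules$mono_shift)
  rules[, c("name", "formula_delta", "mono_shift", "nominal_shift",
            "phase", "rt_direction")]
}

#' Parent-compound reference for annotation
#'
#' The reference the annotator measures mass shifts and retention-time
#' polarity against: the parent's protonated-molecule m/z and retention
#' time, plus the neutral-loss units used for fragment evidence. The
#' default is the alpha-mangostin survey reference (m/z 411.21, RT 27.6
#' min) with a single prenyl (C4H8, 56.0626 Da) loss unit of multiplicity
#' up to 2; the quantitation assay's parent m/z 411.14 can be substituted.
#'
#' @param parent_mz parent \[M+H\]+ m/z, Da.
#' @param parent_rt parent retention time, min.
#' @param neutral_loss_units named numeric vector of neutral-loss masses
#'   (Da).
#' @param max_loss_multiplicity how many consecutive losses of each unit
#'   to consider.
#' @return A list of class `parent_spec`.
#' @export
parent_spec <- function(parent_mz = 411.21, parent_rt = 27.6,
                        neutral_loss_units = c(prenyl = PRENYL_MASS),
                        max_loss_multiplicity = 2L) {
  if (parent_mz <= 0) abort_adme("`parent_mz` must be > 0", "admekit_bad_mz")
  structure(list(parent_mz = parent_mz, parent_rt = parent_rt,
                 neutral_loss_units = neutral_loss_units,
                 max_loss_multiplicity = as.integer(max_loss_multiplicity)),
            class = "parent_spec")
}

# Diagnostic fragment m/z templates for a precursor assigned to `rule_name`
# ("parent" for the unmetabolized compound). All classes lose the prenyl
# unit (x1, x2); glucuronides additionally lose the glycone(s) and show the
# aglycone-minus-prenyl cascade.
fragment_templates <- function(rule_name, precursor_mz,
                               parent = parent_spec()) {
  gluc <- formula_mono_mass("+C6H8O6")
  losses <- c(outer(seq_len(parent$max_loss_multiplicity),
                    parent$neutral_loss_units))
  if (rule_name == "glucuronidation") {
    losses <- c(losses, gluc, gluc + c(outer(seq_len(parent$max_loss_multiplicity),
                                             parent$neutral_loss_units)))
  } else if (rule_name == "bis_glucuronidation") {
    prenyls <- c(outer(seq_len(parent$max_loss_multiplicity),
                       parent$neutral_loss_units))
    losses <- c(losses, gluc, 2 * gluc, gluc + prenyls, 2 * gluc + prenyls)
  }
  sort(unique(precursor_mz - losses), decreasing = TRUE)
}
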