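#' Grouped parameter values across dose levels
#'
#' Container for one pharmacokinetic parameter observed per subject at
#' several dose levels, the unit of the dose-proportionality tests.
#'
#' @param parameter parameter name (e.g. `"auc_norm"`).
#' @param groups named list: dose label -> numeric vector of per-subject
#'   values.
#' @param alpha significance level for downstream verdicts (default
#'   0.05).
#' @return A list of class `grouped_parameter` with a tidy `data` tibble
#'   (`dose`, `value`).
#' @export
#' @examples
#' grouped_parameter("auc_norm", list(`5` = c(30, 34), `10` = c(31, 33)))
grouped_parameter <- function(parameter, groups, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || !all(nzchar(names(groups)))) {
    abort_adme("`groups` must be a named list of numeric vectors",
               "admekit_bad_groups")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_adme("`alpha` must lie in (0, 1)", "admekit_bad_alpha")
  }
  data <- dplyr::bind_rows(lapply(names(groups), function(g) {
    tibble::tibble(dose = g, value = as.numeric(groups[[g]]))
  }))
  data$dose <- factor(data$dose, levels = names(groups))
  structure(list(parameter = parameter, data = data, alpha = alpha),
            class = "grouped_parameter")
}

check_groups <- function(gp, min_groups = 2L, min_per_group = 2L) {
  counts <- table(gp$data$dose)
  if (length(counts) < min_groups) {
    abort_adme(sprintf("need at least %d groups", min_groups),
               "admekit_too_few_groups")
  }
  if (any(counts < min_per_group)) {
    abort_adme(sprintf("every group needs at least %d values", min_per_group),
               "admekit_too_few_values")
  }
  invisible(gp)
}

#' Group summary in study presentation conventions
#'
#' Mean and SD per dose group, or median with range when
#' `style = "median_range"` (the convention for Tmax).
#'
#' @param gp a [grouped_parameter()].
#' @param style `"mean_sd"` (default) or `"median_range"`.
#' @return Tibble: `parameter`, `dose`, `n`, then `mean`/`sd` or
#'   `median`/`range_lo`/`range_hi`, and a `label` formatted as printed
#'   study tables do.
#' @export
#' @examples
#' group_summary(grouped_parameter("tmax", list(`10` = c(15, 60, 120))),
#'               style = "median_range")
group_summary <- function(gp, style = c("mean_sd", "median_range")) {
  style <- match.arg(style)
  check_groups(gp, min_groups = 1L, min_per_group = 1L)
  by_dose <- split(gp$data$value, gp$data$dose)
  rows <- lapply(names(by_dose), function(d) {
    v <- by_dose[[d]]
    if (style == "mean_sd") {
      tibble::tibble(parameter = gp$parameter, dose = d, n = length(v),
                     mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                     label = sprintf("%.3g ± %.3g", mean(v),
                                     if (length(v) > 1) sd(v) else 0))
    } else {
      tibble::tibble(parameter = gp$parameter, dose = d, n = length(v),
                     median = median(v), range_lo = min(v),
                     range_hi = max(v),
                     label = sprintf("%g (%g–%g)", median(v), min(v),
                                     max(v)))
    }
  })
  dplyr::bind_rows(rows)
}

#' One-way ANOVA across dose groups
#'
#' Classical fixed-effects one-way analysis of variance (equal variances)
#' of the parameter values across at least three dose groups, via
#' [stats::aov()].
#'
#' @param gp a [grouped_parameter()] with >= 3 groups of >= 2 values.
#' @return List: `f_stat`, `p_value`, `df` (between, within), `fit` (the
#'   aov object, for Tukey follow-up).
#' @export
one_way_anova <- function(gp) {
  check_groups(gp, min_groups = 3L)
  fit <- aov(value ~ dose, data = gp$data)
  tab <- summary(fit)[[1]]
  list(f_stat = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
       df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
       fit = fit)
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' Studentized-range pairwise dose-group comparisons on the ANOVA
#' residual variance, via [stats::TukeyHSD()].
#'
#' @param gp a [grouped_parameter()] with >= 3 groups.
#' @return Tibble: `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(gp) {
  fit <- one_way_anova(gp)$fit
  tk <- TukeyHSD(fit)$dose
  tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                 lwr = tk[, "lwr"], upr = tk[, "upr"],
                 p_adj = tk[, "p adj"])
}

#' Unpaired two-sample Student t-test
#'
#' Classical two-sided t-test assuming equal variances, for parameters
#' observed at exactly two dose levels.
#'
#' @param gp a [grouped_parameter()] with exactly 2 groups.
#' @return List: `t_stat`, `p_value`, `df`.
#' @export
two_sample_t <- function(gp) {
  check_groups(gp, min_groups = 2L)
  if (nlevels(gp$data$dose) != 2L) {
    abort_adme("t-test requires exactly 2 groups", "admekit_bad_groups")
  }
  v <- split(gp$data$value, gp$data$dose)
  tt <- t.test(v[[1]], v[[2]], var.equal = TRUE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Dose-independence verdict for a dose-normalized parameter
#'
#' Declares a parameter dose-independent when the omnibus test across
#' dose groups (one-way ANOVA for three or more groups, Student t-test
#' for two) is non-significant at `alpha`. Tukey pairwise comparisons
#' are attached as evidence detail when applicable; they do not drive
#' the verdict.
#'
#' @param gp a [grouped_parameter()] holding dose-normalized per-subject
#'   values at >= 2 dose levels.
#' @return List of class `linearity_verdict`: `parameter`, `verdict`
#'   (`"dose_independent"`/`"dose_dependent"`), `test`, `statistic`,
#'   `p_value`, `alpha`, `evidence` (tidy tibble: parameter, comparison,
#'   statistic, p, verdict).
#' @export
#' @examples
#' gp <- grouped_parameter("auc_norm",
#'   list(`5` = c(30, 34, 36), `10` = c(31, 33, 30), `20` = c(29, 35, 32)))
#' linearity_verdict(gp)
linearity_verdict <- function(gp) {
  check_groups(gp, min_groups = 2L)
  k <- nlevels(droplevels(gp$data$dose))
  if (k < 2L) {
    abort_adme("verdict undefined for a single group",
               "admekit_too_few_groups")
  }
  if (k == 2L) {
    res <- two_sample_t(gp)
    test <- "student_t"
    statistic <- res$t_stat
    p <- res$p_value
    tukey <- NULL
  } else {
    res <- one_way_anova(gp)
    test <- "one_way_anova"
    statistic <- res$f_stat
    p <- res$p_value
    tukey <- tukey_hsd(gp)
  }
  verdict <- if (p < gp$alpha) "dose_dependent" else "dose_independent"
  evidence <- tibble::tibble(parameter = gp$parameter,
                             comparison = "omnibus", test = test,
                             statistic = statistic, p = p,
                             verdict = verdict)
  if (!is.null(tukey)) {
    evidence <- dplyr::bind_rows(
      evidence,
      tibble::tibble(parameter = gp$parameter,
                     comparison = tukey$comparison, test = "tukey_hsd",
                     statistic = tukey$diff, p = tukey$p_adj,
                     verdict = ifelse(tukey$p_adj < gp$alpha,
                                      "different", "not_different"))
    )
  }
  structure(list(parameter = gp$parameter, verdict = verdict, test = test,
                 statistic = statistic, p_value = p, alpha = gp$alpha,
                 evidence = evidence),
            class = "linearity_verdict")
}

#' @export
print.linearity_verdict <- function(x, ...) {
  cat(sprintf("<linearity_verdict> %s: %s (%s, statistic %.3g, p %.3g, alpha %g)\n",
              x$parameter, x$verdict, x$test, x$statistic, x$p_value,
              x$alpha))
  invisible(x)
}
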