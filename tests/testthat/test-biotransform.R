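test_that("rule shifts are recomputed from atomic masses and internally consistent", {
  rules <- build_rule_table()
  shift <- function(nm) rules$mono_shift[rules$name == nm]
  expect_equal(round(shift("methylation"), 3), 14.016)
  expect_equal(round(shift("oxidation"), 3), 15.995)
  expect_equal(round(shift("dehydrogenation"), 3), -2.016)
  expect_equal(round(shift("glucuronidation"), 4), 176.0321)
  expect_equal(shift("bis_glucuronidation"), 2 * shift("glucuronidation"),
               tolerance = 1e-12)
  expect_equal(shift("hydrogenation"), -shift("dehydrogenation"),
               tolerance = 1e-12)
  expect_identical(rules$rt_direction[rules$name == "methylation"], "later")
  expect_identical(sum(rules$rt_direction == "later"), 1L)
})

test_that("formula parser handles signs, counts and bad input", {
  expect_equal(formula_mono_mass("+O"), 15.9949146221)
  expect_equal(formula_mono_mass("-H2"), -2 * 1.0078250319)
  expect_equal(formula_mono_mass("C6H8O6"),
               6 * 12 + 8 * 1.0078250319 + 6 * 15.9949146221)
  expect_error(formula_mono_mass("+X2"), class = "admekit_unknown_element")
  expect_error(formula_mono_mass("+6C"), class = "admekit_bad_formula")
})

test_that("peak matching ranks rules by mass error with parent short-circuit", {
  parent <- parent_spec(parent_mz = 411.14)
  m <- match_peak(587.17, parent)
  expect_identical(m$rule[1], "glucuronidation")
  expect_equal(m$nominal_shift[1], 176)
  p <- match_peak(411.14, parent)
  expect_identical(p$rule, "parent")
  expect_equal(p$mass_error, 0)
  b <- match_peak(763.21, parent)
  expect_identical(b$rule[1], "bis_glucuronidation")
  expect_equal(b$nominal_shift[1], 352)
  u <- match_peak(500.0, parent)
  expect_identical(u$rule, "unassigned")
  expect_true(is.na(u$mass_error))
  expect_error(match_peak(587, tolerance_da = 0),
               class = "admekit_bad_tolerance")
})

test_that("ambiguous shifts report every candidate ranked by error", {
  # a +15.0 Da shift sits between methylation (+14.016) and oxidation
  # (+15.995); a 1 Da tolerance admits both candidates, nearer one first
  parent <- parent_spec(parent_mz = 400)
  wide <- match_peak(415.0, parent, tolerance_da = 1.0)
  expect_identical(nrow(wide), 2L)
  expect_true(!is.unsorted(abs(wide$mass_error)))
  expect_identical(wide$rule[1], "methylation")
})

test_that("fragment evidence counts diagnostic neutral losses once each", {
  parent <- parent_spec(parent_mz = 411.21)
  expect_identical(fragment_evidence(c(354.85, 299.19), 411.21, "parent",
                                     parent), 2L)
  expect_identical(fragment_evidence(numeric(), 587.04, "glucuronidation",
                                     parent), 0L)
  expect_identical(fragment_evidence(c(531.18, 411.05, 354.86), 587.04,
                                     "glucuronidation", parent), 3L)
  # an uninformative fragment does not count
  expect_identical(fragment_evidence(c(104.30), 587.17, "glucuronidation",
                                     parent), 0L)
  # bis-glucuronide cascade
  expect_identical(fragment_evidence(c(707.15, 587.06, 530.99, 411.23,
                                       355.10), 763.21,
                                     "bis_glucuronidation", parent), 5L)
})

test_that("retention-time polarity flags follow class direction", {
  parent <- parent_spec(parent_rt = 27.6)
  expect_true(rt_consistency(28.2, parent, "methylation"))
  expect_false(rt_consistency(27.0, parent, "methylation"))
  expect_true(rt_consistency(27.6, parent, "dehydrogenation"))  # co-elution
  expect_false(rt_consistency(30.0, parent, "glucuronidation"))
  expect_true(is.na(rt_consistency(10, parent, "parent")))
  expect_error(rt_consistency(10, parent, "sulfation"),
               class = "admekit_unknown_rule")
})

test_that("the published mouse metabolite survey is annotated class-for-class", {
  peaks <- amg_metabolite_peaks()
  ann <- annotate_peaklist(peaks[, 1:5], parent_spec(411.21, 27.6),
                           tolerance_da = 0.5)
  expect_identical(nrow(ann), 16L)
  merged <- merge(ann, peaks[, c("peak_id", "reaction")], by = "peak_id")
  expect_identical(merged$rule, merged$reaction)
  expect_true(all(ann$rt_consistent[ann$rule != "parent"]))
  expect_true(all(abs(ann$mass_error_da) <= 0.5, na.rm = TRUE))
  # deterministic ordering by RT then m/z
  expect_true(!is.unsorted(ann$rt_min))
  # duplicate ids rejected; empty list allowed
  dup <- peaks[c(1, 1), 1:5]
  expect_error(annotate_peaklist(dup), class = "admekit_duplicate_peak")
  empty <- annotate_peaklist(peaks[0, 1:5])
  expect_identical(nrow(empty), 0L)
})

test_that("annotation is tolerance-monotone", {
  peaks <- amg_metabolite_peaks()[, 1:5]
  tols <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  n_assigned <- vapply(tols, function(tol) {
    ann <- annotate_peaklist(peaks, tolerance_da = tol)
    sum(!ann$rule %in% "unassigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("annotation round-trips the synthetic peak-list generator", {
  rules <- build_rule_table()
  sp <- peaklist_spec(parent_mz = 411.21, parent_rt = 27.6,
                      reactions = rules$name, mz_noise_sd = 0, seed = 2)
  pl <- simulate_peaklist(sp)
  ann <- annotate_peaklist(pl, parent_spec(411.21, 27.6))
  got <- ann$rule[match(pl$peak_id, ann$peak_id)]
  expect_identical(got, c("parent", rules$name))
  expect_false(any(ann$rule == "unassigned"))
  expect_true(all(ann$rt_consistent[ann$rule != "parent"]))
  expect_true(all(ann$fragment_evidence[ann$rule != "unassigned"] > 0))
  # subset round trip, as independent draws
  sp2 <- peaklist_spec(reactions = c("oxidation", "methylation"), seed = 5)
  ann2 <- annotate_peaklist(simulate_peaklist(sp2))
  expect_setequal(ann2$rule, c("parent", "oxidation", "methylation"))
})
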