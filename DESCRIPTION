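Package: admekit
Title: Noncompartmental Pharmacokinetics, ADME Metrics and Metabolite
    Mass-Shift Annotation for Mouse Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for small-molecule ADME studies in mice:
    non-compartmental pharmacokinetic analysis (AUC/AUMC by linear or
    linear-up/log-down trapezoids, terminal-slope selection by adjusted
    R-squared, clearance, steady-state volume, bioavailability and
    dose-normalization), dose-proportionality testing (classical ANOVA
    with Tukey multiple comparisons), derived ADME metrics
    (tissue-to-plasma partitioning, equilibrium-dialysis protein binding,
    unbound renal clearance, fraction-unabsorbed correction, S9 metabolic
    stability, excretion recoveries), and tentative metabolite
    identification by biotransformation mass-shift matching with
    diagnostic neutral-loss and retention-time evidence. A synthetic-data
    module simulates every input kind (two-compartment intravenous bolus
    and first-order-absorption oral kinetics with log-normal
    between-subject variability, proportional residual error and LLOQ
    censoring, plus excretion, dialysis, S9 and MS peak-list records) so
    the whole pipeline is testable without animal data. Defaults are
    calibrated to the mouse pharmacokinetics of the xanthone
    alpha-mangostin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
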