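---
title: "Methods: noncompartmental PK, ADME metrics and metabolite mass-shift annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncompartmental PK, ADME metrics and metabolite mass-shift annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admekit)
```

admekit implements the computational chain of a mouse ADME study of a
poorly absorbed, extensively metabolized small molecule — calibrated
throughout to alpha-mangostin, a prenylated xanthone — as reusable,
tested functions. This vignette is the package's account of the models
and the choices behind them.

## The disposition model and its simulator

Plasma kinetics are simulated from a two-compartment model parameterized
by micro-constants: clearance CL (mL/min/kg), central volume V1 (mL/kg),
inter-compartmental clearance Q, and peripheral volume V2. With
$k_{10} = CL/V_1$, $k_{12} = Q/V_1$, $k_{21} = Q/V_2$, the disposition
exponents $\alpha \ge \beta$ are the roots of
$s^2 + (k_{10}+k_{12}+k_{21})s + k_{10}k_{21} = 0$, and an intravenous
bolus follows $C(t) = A e^{-\alpha t} + B e^{-\beta t}$ with
$A + B = \mathrm{dose}/V_1$. The oral curve is the convolution with
first-order absorption at rate $k_a$, dose scaled by the bioavailable
fraction $F$; flip-flop kinetics ($k_a < \beta$) are allowed, and the
degenerate case $k_a = \alpha$ or $\beta$ is handled by perturbing
$k_a$ by a relative $10^{-6}$ with a warning.

The micro-constant parameterization was chosen deliberately: every
noncompartmental quantity the pipeline later estimates has a closed form
in it (AUC $= F\cdot\mathrm{dose}/CL$, $V_{ss} = V_1 + V_2$, terminal
half-life $= \ln 2/\beta$), so the simulator doubles as an analytic
oracle for the NCA code.

Default parameters are calibrated to the observed mouse disposition of
alpha-mangostin: CL = 31.4 mL/min/kg and $V_{ss}$ = 4304 mL/kg, with the
split V1 = 1000, V2 = 3304 mL/kg and Q = 15 mL/min/kg selected so the
terminal half-life lands near the observed ~226 min (the study reports
the CL/Vss pair, not the individual compartment constants, which are not
identifiable from a published summary table). Between-subject
variability is log-normal, applied independently to CL, V1, Q, V2 and
$k_a$ with a common log-SD `omega` (default 0.25, matching the ~25–45%
CVs of the study's parameter table); no inter-parameter correlation is
imposed because none is reported. Residual error is proportional only
(default SD 0.10), with the 1 ng/mL quantitation limit standing in for
an additive error floor: simulated values below LLOQ are flagged
censored, never dropped or zeroed. Sampling schedules default to the
study's designs (0–360 min, twelve IV and eleven oral points).

One consequence of log-normal parameter variability worth knowing when
interpreting simulations: because $E[k_i] = k\,e^{\omega^2}$ for the
log-normally distributed elimination rate, the *geometric-mean*
concentration of a population decays slightly faster than the curve of
the median subject — about 4% lower at $t k \approx 0.44$ for
$\omega = 0.3$. The simulator tests check the geometric mean against its
closed form, not against the median curve.

Excretion recoveries (urinary `Ae` and gastrointestinal `GI` percent of
dose at 24 h) are drawn log-normally around the true fractions with unit
mean and CV `excretion_cv` (default 0.6, the spread of the observed
recoveries). Tissue concentrations, where needed, are plasma times a
target tissue-to-plasma ratio — the generator makes no mechanistic
(PBPK) claim. Dialysis pairs satisfy
`buffer = fu * plasma` at equilibrium; S9 incubations deplete
first-order, `remaining = spiked * exp(-k * 30 min)`. Synthetic peak
lists place one precursor per requested biotransformation at
parent m/z + monoisotopic shift, carrying that class's diagnostic
neutral-loss fragments and a retention-time offset drawn uniformly in
[-12, -1] min (all classes) or [+0.3, +1] min (methylation), matching
the observed elution window. What passing round-trip tests on these data
show is internal consistency of the pipeline under its own assumptions —
they cannot certify behaviour on real chromatograms (peak shape,
isotope interference) or on kinetics outside the two-compartment family.

## Noncompartmental analysis

`auc_trapezoid()` implements the plain linear and the linear-up/log-down
trapezoid; the latter is the default, the standard choice for bolus
decline. Log interpolation is used only on segments where both
concentrations are positive and strictly decreasing, so the two methods
agree exactly on flat segments and log-down never exceeds linear on a
decline. Leading below-LLOQ samples (pre-absorption) enter as zeros so
the rising limb is anchored; embedded and trailing censored points are
excluded, and integration stops at the last quantifiable sample.

`fit_lambda_z()` regresses log concentration on time over every suffix
of at least three quantifiable post-Cmax points — Cmax itself included
for an IV bolus, excluded for the oral route — and keeps the window with
the best adjusted $R^2$, ties broken toward more points. This mirrors
common NCA-software practice; the calibrating study does not state its
selection rule, so the choice is recorded in the fit output
(`lambda_z_npoints`, `lambda_z_r2adj`). A non-negative slope in every
window flags the half-life as not estimable; the extrapolated
quantities are then `NA` while `auc_last` is still reported. The
regressions over all suffixes are computed from reverse cumulative sums,
so dense (minute-resolution) profiles cost O(n), not O(n²).

`nca_single()` assembles the parameter set:
$AUC_\infty = AUC_{last} + \hat{C}_{last}/\lambda_z$ with
$\hat{C}_{last}$ predicted from the terminal fit (not the noisy observed
value), $MRT = AUMC_\infty/AUC_\infty$, $CL = \mathrm{dose}/AUC_\infty$
and $V_{ss} = CL \cdot MRT$ for the bolus route, Cmax/Tmax read directly
from observed points with no interpolation, renal clearance
$CL_R = A_{e,0-24}/AUC_\infty$ from the excretion record, and
$CL_{NR} = CL - CL_R$ exactly. The observed $t=0$ sample is used when
present (the calibrating design samples at 0); back-extrapolation from
the first two points would be used only if it were missing. Group
statistics are means ± SD of per-subject parameters — not parameters of
the mean profile — which is the only convention that reconciles a
dose-normalized group AUC with its per-dose group AUC; Tmax is
summarized as median (range).

At desk scale the package cannot re-derive the study's per-animal
means and SDs — the per-animal concentration data were never deposited —
so the tests assert recovery properties instead: on noise-free dense
bolus profiles over 20 random parameter draws, NCA recovers CL within 2%
and $V_{ss}$ within 5% (measured errors are ~0.01%); on the sparse
study schedule, CL within 5% and terminal half-life within 10% with
AUC extrapolation under 20%.

## Dose-proportionality testing

Dose-normalized per-subject values (value × 1 mg·kg⁻¹/dose) are compared
across dose groups with the classical equal-variance tests the study
names: one-way ANOVA for three or more groups (Student t for two), with
Tukey HSD pairwise comparisons attached as evidence. The verdict —
`dose_independent` versus `dose_dependent` — keys on the omnibus p-value
at `alpha` (default 0.05); Tukey never drives it. Whether the original
analysis normalized per animal or per group is not stated; per-animal
normalization is assumed, consistent with the normalized rows of the
published table. The tests validate the machinery against hand-computed
sums of squares, permutation oracles (agreement within 0.02 in p), a
1000-replicate null simulation (type-I error 0.03–0.07), and a
specificity check (≥ 90% dose-independent verdicts on truly proportional
simulated groups; a 3× shifted group is always flagged).

## Derived ADME metrics

* **Tissue partitioning.** T/P = homogenate concentration ×
  dilution factor / plasma. The homogenization recipe (one part tissue,
  four volumes water) implies a default factor of 5; the study reports
  T/P without stating its correction, so the factor is an argument.
  Ratios above 1 are tagged high-affinity.
* **Protein binding.** From an equilibrium-dialysis pair,
  fu = buffer/plasma and bound% = 100·(1 − fu). Buffer above plasma is
  physically impossible and is flagged, not rejected.
* **Unbound renal clearance.** $CL_{R,fu} = CL_R/fu$, compared with the
  mouse glomerular filtration rate (reference constant 14.0 mL/min/kg).
  For the calibration values this spans 1.72–3.45 mL/min/kg across IV
  dose groups; the upper endpoint computed from bound% = 91.8 is 3.45,
  while the source prints 3.44 — its unrounded fu is unknown, so the
  computed value is reported.
* **Fraction unabsorbed.** The default subtractive correction
  $F_{unabs} = GI_{24,oral} - F \cdot GI_{24,iv}$ removes the
  post-absorptive (biliary/intestinal) component from the oral GI
  recovery; it reproduces the calibration value 0.434 from the group
  fractions. A normalized variant dividing by $(1-F)$ is selectable,
  since the originating correction formula is cited but not reproduced
  in the study; at $F = 2.3\%$ the two differ by ~1%.
* **S9 stability.** disappearance% = 100·(1 − remaining/spiked), with
  apparent negative disappearance clipped to 0 with a warning.

## Metabolite mass-shift annotation

`build_rule_table()` defines six biotransformation classes —
glucuronidation (+C6H8O6), bis-glucuronidation (+C12H16O12),
dehydrogenation (−H2), hydrogenation (+H2), oxidation (+O) and
methylation (+CH2) — with monoisotopic shifts recomputed from a bundled
atomic-mass table at call time. The recomputed glucuronide shifts
(176.0321 / 352.0642 Da) are authoritative over the 176.034 / 352.068
sometimes printed for this assay; nominal integer shifts are used for
reporting parity.

`match_peak()` assigns a precursor to the rule minimizing the absolute
mass error within a tolerance (default 0.5 Da — unit-resolution
triple-quadrupole data, where observed survey errors reach ~0.36 Da);
peaks within tolerance of the parent m/z are "parent", peaks matching
nothing are "unassigned" (a valid outcome). Ties are all reported,
ranked. `fragment_evidence()` counts observed product ions matching the
class's diagnostic neutral-loss templates: loss of the prenyl side
chain C4H8 (56.0626 Da, ×1 or ×2) for every class, plus glycone losses
and the aglycone-minus-prenyl cascade for the glucuronides; each
observed fragment counts once. `rt_consistency()` flags elution-order
plausibility — phase I/II metabolites are more polar and elute earlier
on reversed phase, methylation later; co-elution counts as consistent
for "earlier" classes. The flag is reported, never used as a filter,
because elution order is supporting evidence, not proof. Positional
isomers (e.g. the three glucuronides) are deliberately not
distinguished: mass shift plus neutral losses cannot separate them.

On the bundled 16-peak survey fixture (parent m/z 411.21, RT 27.6 min)
the annotator reproduces the published reaction class of all 15
metabolites at 0.5 Da tolerance, and annotation is tolerance-monotone:
shrinking the tolerance never adds assignments.

## Numerical and design notes

* Units are fixed (min, µg/mL, mg/kg, mL/min/kg, mL/kg, Da); conversion
  happens only at IO boundaries. Doses in mg/kg are converted to µg/kg
  internally so clearances come out in mL/min/kg directly.
* All randomness flows from explicit seeds carried in the spec objects;
  identical spec + seed reproduces identical output.
* Validation failures raise classed conditions (`admekit_*`) so callers
  can catch specific failure modes; physically impossible but
  observable data (buffer > plasma, remaining > spiked, $F_{unabs}$
  outside [0, 1]) are flagged with warnings rather than rejected.
* Problem sizes in the test suite and acceptance script — 20 parameter
  draws for NCA recovery, 500 subjects for the population geometric-mean
  check, 1000 null replicates for the type-I error — were chosen as the
  smallest sizes at which the Monte-Carlo error is comfortably below the
  asserted tolerances.
* Known limitations: no compartmental fitting to data, no
  sparse-sampling NCA, no nonlinear protein binding, no isotope-pattern
  or in-silico fragmentation scoring, no chromatogram peak picking, and
  the simulator's tissue module is a ratio model, not PBPK.
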