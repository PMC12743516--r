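---
title: "Methods: phenotype-stratified activity and cardiovascular outcomes in AF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-stratified activity and cardiovascular outcomes in AF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the decisions taken where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## The scientific question

Atrial fibrillation (AF) patients differ widely in comorbidity burden, and
physical-activity guidance rarely distinguishes between AF phenotypes. The
pipeline asks: is accelerometer-measured moderate-to-vigorous physical
activity (MVPA, min/week) associated with lower incidence of major adverse
cardiovascular events (MACE: cardiac arrest, stroke, heart failure,
myocardial infarction, ischaemic heart disease), and does the association
look similar in a "low risk" and a "high risk" comorbidity phenotype?

## Accelerometry

**Signal model.** Wrist devices record tri-axial acceleration in
milligravity (mg) at a nominal 100 Hz within ±8 g. Activity intensity is
summarised per 5-s epoch as ENMO — the Euclidean norm of the calibrated
signal minus one gravity, truncated at zero, averaged over the epoch's
samples (truncation is applied per sample; the trailing partial epoch is
dropped). ENMO is used because the conventional 100 mg MVPA cut is defined
on that scale; a raw vector norm would make the cut meaningless.

**Calibration.** Offsets and gains per axis are estimated from stationary
windows (10 s, all three axis SDs < 13 mg) by iterating between projecting
stationary means onto the 1000 mg sphere and regressing each axis on its
raw values. Gains are only identifiable when stationary postures span
different orientations; an axis without such spread receives an offset-only
update. Fewer than 10 stationary windows aborts calibration with a warning
flag that QC records, rather than failing the pipeline. A pre-aggregated
epoch-mode series (sampling rate < 1 Hz) is assumed already calibrated,
since within-epoch variation needed by the sphere fit is gone.

**Non-wear.** The published rule is an episode rule only (≥ 60 min with all
axis SDs < 13 mg). The windowing mechanics are this package's decision: a
60-min window slides in 15-min steps, a window is stationary if all three
raw-axis SDs are below the cut, overlapping stationary windows merge, and
merged spans of at least 60 min become non-wear. Consequently detected
boundaries are resolved to the 15-min step grid, which is what the
recovery tests assert.

**Classification and weekly summary.** Non-wear epochs are excluded; MVPA
requires epoch ENMO *strictly above* 100 mg (an epoch at exactly 100.0 mg
is not MVPA); the sedentary/light boundary is unstated in the source design
and set to the conventional 30 mg companion cut (configurable); ties break
toward the lower intensity. Wear time below 3 valid days (wear seconds /
86400) fails QC. Whether the source scaled minutes to a 7-day week or
averaged per valid day is unstated; both are implemented
(`scale = "week"`, the default, multiplies by `7 / valid_wear_days`;
`"per_day"` reports the per-day average) and the default is documented
everywhere it appears.

## Phenotyping

Thirty-one binary indicators feed the clustering: six derived from
continuous measurements — age ≥ 60 y, BMI ≥ 25 kg/m², eGFR < 90 (90 itself
is normal), gamma-glutamyl transferase > 40 U/L (40 itself is normal),
anaemia as haematocrit below 37 % (women) / 40 % (men) (the cut itself is
not anaemic), plus sex — and 25 directly binary comorbidity/treatment
flags. Boundary conventions follow the normal/abnormal phrasing of the
clinical cut-points. The encodings for ethnicity (white background y/n),
alcohol (daily use y/n) and smoking (current y/n) are decisions surfaced as
configuration, since only those binary rows appear in the source tables.

Missing entries are imputed by column mode with ties going to 0 — a
deliberate, auditable simplification of an unstated imputation procedure,
flagged prominently; columns more than half missing are refused. Model
covariates for the survival analysis are *not* imputed: rows missing any
adjustment covariate are excluded and counted in the flow log, keeping the
survival estimand free of imputed covariates.

**Ward linkage.** Agglomeration starts from singletons and at each step
merges the pair minimising the increase in within-cluster sum of squares,
\(\Delta SSE = \frac{n_i n_j}{n_i + n_j}\lVert c_i - c_j\rVert^2\),
maintained with the Lance–Williams update on squared Euclidean distances.
Binary data produce many exact ties (duplicate rows merge at height 0);
ties are broken toward the lexicographically lowest pair of cluster
creation indices, making the tree fully deterministic and the
oracle-equivalence tests exact. Heights are non-decreasing (Ward is
reducible) and telescope to the pooled SSE — both are tested. Cutting
removes the k−1 final merges; for k = 2 the cluster with the higher mean
indicator burden is named "high risk". The implementation scans the full
distance matrix per merge (O(n²) a step), comfortably fast to a few
thousand individuals; study-scale runs (~5000) take minutes, which is
accepted rather than adding compiled code.

Silhouette diagnostics (squared Euclidean) over k = 2..6 support the
judgement-based choice of k; identical-rows inputs have undefined
silhouettes, reported as `NA`.

## Survival analysis

Follow-up runs from the index date — the later of AF diagnosis and
accelerometry, or of the procedure date and accelerometry in the
rhythm-control subgroup — to the earliest of first qualifying MACE,
dropout, and 6 years (6 × 365.25 days floored, 2191 days). Events dated on
the AF diagnosis day are excluded as outcomes (the individual continues,
censored); an individual whose first event precedes the index is excluded
entirely and logged.

MVPA quartiles are assigned within cluster by rank, sizes as equal as
possible with the remainder going to the *lowest* quartiles (n = 2275
gives 569/569/569/568) and ties broken by stable input order.

The Cox model maximises the Efron-corrected partial likelihood by
Newton–Raphson with step halving. Efron rather than Breslow because
day-resolution follow-up produces ties. Covariates are centred and scaled
internally for conditioning and estimates mapped back. Convergence is
declared when the largest score component falls below 1e−8; at large n the
score cannot be pushed below the summation roundoff floor, so a vanishing
Newton increment (< 1e−10) is also accepted and the achieved score is
reported. Constant covariates and event-free datasets are rejected, never
silently dropped. Quartile exposure enters as indicators for Q2–Q4, so the
reference hazard ratio is identically 1. The adjusted covariate set
defaults to the statistical-methods text (age, sex, sedentary time, HF,
heart disease, T2D, BMI, smoking, hypertension); the figure-caption
variant adding ethnicity and alcohol is available as
`adjustment = "extended"` because the source is ambiguous about the
operative set. Cluster fits are compared by 95 % CI overlap per term.

## Dose-response

MACE counts are modelled per individual (the first-event indicator in the
pipeline; arbitrary non-negative counts are accepted) by log-linear Poisson
regression on a 3-knot restricted cubic spline of MVPA in the Harrell
truncated-power form, linear by construction outside the outer knots.
Knots sit at the 10/50/90 percentiles of observed MVPA over a 0–300
min/week range. A log person-time offset is on by default — total counts
over variable follow-up are not comparable without exposure time — while
`person_time = NULL` reproduces the literal plain-counts description. The
fit is IRLS with deviance-change convergence at 1e−10; divergence
(separation) is a reported failure, not a wrong answer.

Linearity is a 1-df Wald chi-square on the nonlinear coefficient. The IRR
curve is `exp(η(d) − η(ref))` with delta-method variance `gᵀΣg` on the
log scale; the reference dose defaults to the minimum observed MVPA
("lowest MVPA levels"), configurable to 0. The grid step is 1 min/week so
thresholds resolve to the minute.

**Thresholds.** The minimal dose is the smallest grid dose above the
reference whose IRR vs the reference has a 95 % CI excluding 1. The
optimal-dose clause in the source design is grammatically ambiguous; the
implemented reading compares each dose d to d − 30 min/week (10 % of the
0–300 range) and reports the first non-significant step — the point where
an extra 30 min/week stops buying a significant further reduction
("maximum benefit for least effort"). The alternative reading (step
through the grid in 30-min increments comparing to the reference) is
available as `mode = "vs_reference"`. The scanner is a pure function of
the IRR/CI arrays and is tested against an exhaustive brute-force loop.
Note that with very large samples the minimal dose lands close to the
reference — adjacent-dose contrasts have tiny variance — so its location
is a statement about precision as much as about curve shape.

## Synthetic data: the stated world

The generator's defaults encode the study-scale conditions: n = 4858 with
a 53 % high-risk share; log-normal weekly MVPA with median ≈ 105 min/week
(log-SD 0.55, matching the spread of the published quartile medians) and a
−0.25 log-shift in the high-risk phenotype (lower activity at higher
burden, as the quartile tables show); per-variable indicator prevalences
chosen qualitatively from the two clusters' published tables; a baseline
hazard of 0.022/year giving mid-single-digit to low-double-digit six-year
cumulative incidence by phenotype; a cluster log-hazard ratio of
log(3.81); exponential dropout at 0.02/year independent of covariates
(only administrative censoring is specified at 6 years; independence keeps
the recovery estimand clean); and a protective dose effect on the same
spline basis the dose-response module fits, with knots (25, 100, 220) and
coefficients (−0.0155, 0.01343) constructed so the log-hazard declines
steeply to about 100 min/week (IRR ≈ 0.32 vs the least active, matching
the published magnitude qualitatively) and is *exactly* flat beyond the
last knot. Two published table rows are not reproduced because they are
internally inconsistent (anaemia at 100 % in every column; hypertension at
~0.2 % against 18–48 % anti-hypertensive use); hypertension defaults to
0.35/0.60 by phenotype instead.

Continuous measurements are Gaussian per phenotype with means back-solved
by probit inversion so dichotomized prevalences hit their targets — only
threshold-crossing probabilities matter downstream. Dates are days since
an arbitrary epoch, accelerometry uniform within 5 years after diagnosis.
Recordings place a 1000 mg gravity vector along a per-segment axis-aligned
orientation plus a class-level acceleration and per-axis noise (sedentary
5 mg level / 26 mg SD, light 65/26, MVPA 150/18, non-wear 0/2). The worn
SDs sit far enough above the 13 mg stationarity cut that non-wear
boundaries blur by less than one 15-min step; MVPA noise is moderate so
single-epoch misclassification across the strict 100 mg cut is negligible
even in the decimated epoch mode (one sample per 5 s) used for fast
week-long tests.

**What the generator does not emulate** — and hence what a green test does
not establish: realistic correlations among comorbidities beyond the
two-phenotype structure (independence given phenotype), device artefacts
(temperature drift, clock jitter), activity autocorrelation within days,
time-varying activity, or covariate-dependent dropout. Cluster recovery at
the *default*, weakly separated prevalences is far from perfect, so
pipeline runs on defaults show a diluted cluster contrast; recovery
guarantees are stated (and tested) for the separated world with ten
indicators at 0.05 vs 0.60 prevalence.

## Numerical choices

- Cox: score tolerance 1e−8, ≤ 100 Newton iterations with step halving,
  internal covariate standardisation, Efron ties.
- Poisson IRLS: deviance tolerance 1e−10; divergence detected via
  non-finite deviance or vanishing means.
- Ward: exact tie-break by creation-index pairs; heights are ΔSSE.
- Thresholds: 1 min/week grid; two-sided 95 % CIs throughout.
- Percentages reported in tables round half away from zero (0.5 % → 1 %),
  matching printed-table conventions rather than banker's rounding.
- Quartile remainder individuals go to the lowest quartiles, reproducing
  the published 569/569/569/568 and 339/339/338/338 splits.

## Known limitations

- Mode imputation understates uncertainty relative to model-based
  imputation; it is deterministic and auditable, which the testing story
  privileges.
- The Ward implementation is plain R; study-scale (~5000) clustering takes
  minutes. Tests run at a few hundred to 1500 individuals.
- The chi-square test used for binary rows in characteristics tables is a
  documented deviation: the source names only t-tests/ANOVA, which cannot
  apply to count rows.
- The minimal/optimal dose locations depend on sample size through CI
  width; they are decision rules on an estimated curve, not curve
  features.
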