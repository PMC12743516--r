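# afmvpa

Phenotype-stratified analysis of accelerometer-derived physical activity and
major adverse cardiovascular events (MACE) in atrial fibrillation (AF).

AF is a heterogeneous condition: comorbidity burden varies widely between
patients, and activity guidance that treats the population as homogeneous may
miss phenotype-specific patterns. This package re-implements, as a tested and
reusable pipeline, the full analysis design of a cohort study of that
question — from raw wrist acceleration to dose-response thresholds — and
ships a synthetic-cohort generator with known ground truth so that every
stage can be exercised and validated without access to restricted cohort
data.

## What the pipeline does

1. **Accelerometry** — tri-axial wrist signal (100 Hz, ±8 g) is calibrated
   to gravity, collapsed into 5-s ENMO epochs
   (`max(0, ||(x,y,z)|| − 1000 mg)`), screened for non-wear (≥ 60 min with
   all three axis SDs < 13 mg), classified (MVPA strictly > 100 mg;
   light 30–100 mg), and summarised as weekly minutes with a ≥ 3 wear-day
   quality gate.
2. **Phenotyping** — 31 binary comorbidity/risk indicators (continuous
   measurements dichotomized at clinical cut-points: age 60 y, BMI 25 kg/m²,
   eGFR 90, GGT 40 U/L, haematocrit 37 %/40 % by sex) are mode-imputed and
   clustered by Ward minimum-variance agglomeration on squared Euclidean
   distances; cutting the tree at k = 2 yields a "low risk" and a
   "high risk" phenotype.
3. **Survival** — follow-up runs from the later of AF diagnosis and
   accelerometry (or the rhythm-control procedure date in the subgroup
   analysis), capped at 6 years; within each cluster individuals are split
   into MVPA quartiles (Q1 = least active = reference) and Kaplan–Meier
   curves plus Cox proportional-hazards models (Efron ties, own
   Newton–Raphson solver) are fitted, unadjusted and adjusted for age, sex,
   sedentary time, HF, heart disease, T2D, BMI, smoking and hypertension.
4. **Dose-response** — MACE counts are modelled by Poisson regression with
   a person-time offset on a 3-knot restricted cubic spline of weekly MVPA
   (knots at the 10/50/90 percentiles, range 0–300 min/week); linearity is
   Wald-tested; an incidence-rate-ratio curve with delta-method bands is
   scanned for the **minimal dose** (first dose whose IRR vs the reference
   is significant) and the **optimal dose** (first dose whose IRR vs the
   dose 30 min/week lower becomes non-significant — maximum benefit for
   least effort).

The synthetic-data module generates every input: clinical tables with two
latent phenotypes across the 31 indicators, log-normal weekly MVPA,
exponential proportional-hazards event times whose hazard depends on
phenotype and on a smooth spline function of MVPA, independent dropout,
administrative censoring at 6 years, and raw/epoch-mode recordings with
planted activity bouts and non-wear episodes.

## Worked example

```r
library(afmvpa)
sim    <- simulation_config(n_individuals = 1200, seed = 42)
report <- run_study(run_config(sim = sim))
print(report)
```

```
Study report
============
Flow log:
                 input                qc_fail     missing_covariates
                  1200                      0                     66
         imputed_cells event_on_diagnosis_day     event_before_index
                   246                      7                      0
  nonpositive_followup               analysed
                     0                   1134

Cluster sizes:
high  low
 572  562

Cluster contrast (high vs low risk): HR 1.99 (95% CI 1.34-2.96, p 0.000626)

'high risk' cluster, adjusted quartile HRs (Q1 reference):
 term   coef    se    hr hr_lo hr_hi       p
   Q2 -0.422 0.297 0.656 0.366 1.174 0.15539
   Q3 -1.063 0.396 0.345 0.159 0.751 0.00726
   Q4 -0.795 0.539 0.451 0.157 1.299 0.14033
...
Linearity Wald test: chi2(1) = 2.88, p = 0.0898
minimal dose: 12 min/week (IRR 0.992, 95% CI 0.988-0.996 vs 11.5781)
optimal dose: 165 min/week (IRR 0.806, 95% CI 0.649-1.000 vs 135)
```

Reading it: of 1200 simulated individuals, 66 lacked a complete adjustment
covariate set and 7 carried an event dated on the AF diagnosis day (dropped
per the censoring policy), leaving 1134 analysed. Ward clustering split them
into two phenotypes whose hazard contrast (HR 1.99) reflects the generator's
designed cluster effect diluted by imperfect label recovery at the default,
weakly-separated prevalences. Within both clusters the more-active quartiles
trend protective (HR < 1 vs Q1). The dose-response scan reports the first
significantly-protective dose above the reference and the dose at which an
extra 30 min/week stops buying a significant further reduction.

## Command line

```sh
Rscript inst/cli/afmvpa simulate-cohort --config cfg.yaml --out data/
Rscript inst/cli/afmvpa accel-summarise --in rec.csv --out summary.json
Rscript inst/cli/afmvpa phenotype-cluster --in clinical.csv --k 2 --out labels.csv
Rscript inst/cli/afmvpa survival-fit --records recs.csv --adjusted --out fit.json
Rscript inst/cli/afmvpa dose-fit --records recs.csv --out fit.json
Rscript inst/cli/afmvpa run --config cfg.yaml --out report_dir/
```

## Method validation in the test suite

- Ward linkage is checked merge-for-merge against a naive from-scratch SSE
  agglomeration on 100 random instances (n ≤ 10).
- The Cox solver is checked against a hand-written Efron partial likelihood
  maximised by golden-section search, and against `survival::coxph` to
  ~1e-7 on random tied datasets.
- Poisson IRLS is checked against a Newton maximisation of the written
  likelihood and `glm`; IRR bands against a 2000-rep parametric bootstrap.
- Parameter recovery: cluster labels ≥ 95 % on separated phenotypes;
  log-HR bias < 0.05 at n = 20 000 over 50 replicates for HRs
  0.4/1.0/3.81; Wald linearity type-I error within [0.03, 0.07] over 500
  null replicates; planted non-wear found within one 15-min window step and
  planted MVPA weeks summarised within ±2 min.
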