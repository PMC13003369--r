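# phptfrax

Fracture-risk validation and surgical benefit stratification for primary
hyperparathyroidism (PHPT) cohorts.

PHPT causes progressive bone loss and pathologic fracture; parathyroidectomy
(PTX) is its only durable cure. Clinicians increasingly ask whether a
FRAX-style ten-year fracture-probability score — computed from clinical risk
factors, without bone mineral density — can (a) track observed fracture
incidence in PHPT and (b) identify which patients stand to gain the most
fracture protection from surgery. `phptfrax` implements the full statistical
pipeline behind that question and exercises it end-to-end on seeded
synthetic cohorts, since the EHR data such studies use cannot be
redistributed.

## What the package computes

Given a cohort with covariates, treatment (PTX vs nonsurgical), follow-up
(first fracture by site / death / censoring) and per-patient ten-year MOF
and hip scores in percent:

* **Cumulative incidence** of first fracture with death as a competing
  risk, by the Aalen-Johansen estimator, censoring at loss to follow-up
  (`aalen_johansen()`, `observed_probability_at()`).
* **Calibration**: observed vs estimated ten-year probability by score
  decile, summarised by an unweighted least-squares line — ideal slope 1,
  intercept 0 (`decile_calibration()`), plus a probabilistic-imputation
  sensitivity analysis for the parental hip-fracture item that EHR data
  lack (`impute_parental_history()`, `sensitivity_calibration()`).
* **Discrimination**: time-dependent AUROC with cumulative sensitivity and
  dynamic specificity, inverse-probability-of-censoring weights, and
  influence-function confidence intervals (`td_auroc()`).
* **Treatment-benefit stratification**: a surgical propensity model with
  ATE-style inverse-probability-of-treatment weights balancing covariates
  to standardized mean differences below 0.1 (`fit_propensity()`), then a
  weighted piecewise-exponential Poisson model of the fracture hazard

  ```
  h(t) = exp(b0 + b1 t + b2 age + b3 score + b4 PTX + b5 score x PTX)
  ```

  fitted on person-period data with a log-exposure offset
  (`person_time_expand()`, `fit_poisson_hazard()`). The implied treatment
  hazard ratio HR(score) = exp(b4 + b5 score) is reported as a continuous
  curve with delta-method bands (`hr_curve()`), the smallest score above
  which the upper band stays below 1 is the surgical **benefit threshold**
  (`find_threshold()`), and the score-by-treatment interaction gets a Wald
  test (`interaction_test()`).
* **Synthetic cohorts** with the full statistical structure the analysis
  assumes — realistic covariate marginals, confounded surgical selection,
  cause-specific fracture and Gompertz death hazards, loss to follow-up
  with median follow-up near 2.7 years — plus a transparent surrogate
  ten-year calculator with competing mortality (`generate_cohort()`,
  `surrogate_model()`, `ten_year_probability()`).

`run_pipeline()` orchestrates every stage, writes CSV/JSON outputs and a
reproducible run manifest; `inst/scripts/run_pipeline.R` is a thin
command-line wrapper.

## Worked example

```r
library(phptfrax)
run <- run_pipeline(pipeline_config(n = 50000, seed = 1), outdir = "run")
```

prints, stage by stage:

```
[simulate] 50000 patients, 10230 fracture events, seed 1
[score] 50000 patients scored (median MOF 6.44%, hip 0.99%)
[incidence] observed 10-year incidence: mof 8.04%, hip 1.80%, all 10.43%
[calibrate] mof slope 0.656 intercept 3.30 pp
[calibrate] hip slope 0.336 intercept 1.27 pp
[discriminate] mof AUROC at 10 y: 0.638 (0.618-0.657)
[discriminate] hip AUROC at 10 y: 0.637 (0.599-0.676)
[effects] mof outcome vs mof score: HR at median 0.870, threshold 2.6%
[effects] hip outcome vs hip score: HR at median 0.850, threshold none
[effects] all outcome vs mof score: HR at median 0.886, threshold 2.6%
[effects] all outcome vs hip score: HR at median 0.888, threshold none
[report] 29728 of 50000 (59.5%) meet no guideline surgical criterion
```

Reading the output: the synthetic cohort's median MOF score is 6.44 % while
its observed ten-year MOF incidence is 8.04 % — the score underestimates
risk in this scenario, so the calibration line sits above the diagonal
(intercept 3.3 percentage points). PTX is associated with a hazard ratio of
0.87 for MOF at the median score, and the benefit becomes statistically
consistent (upper confidence bound below 1) above an MOF score of 2.6 %.
The hip-fracture analysis finds a similar point estimate but no threshold:
hip fractures are roughly five times rarer, so at this cohort size the
bands never exclude 1 across the whole score range. The final line counts
patients outside current guideline surgical criteria (age under 50,
osteoporosis, kidney stones, CKD stage 3+) — the population for whom a
score-based threshold would newly signal expected surgical benefit.

All outputs (decile tables, CIF curves, AUROC by year, the HR-by-score
grid and curves, the SMD balance table, JSON summaries, run manifest) are
written under `outdir`.

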