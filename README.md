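# nradjust

Nonresponse-adjusted estimation of post-discharge opioid consumption
quantiles from survey data linked to electronic health record (EHR)
covariates.

## The problem

Opioid prescribing guidelines are increasingly calibrated to *patient-reported
consumption*: the median and 75th percentile of morphine milligram
equivalents (MMEs) actually consumed after discharge, per surgical procedure.
Automated SMS-to-web surveys make this data cheap to collect but respond at
~20%, and responders differ systematically from nonresponders on
characteristics (age, tobacco use, prescription size) that also predict
consumption. Unadjusted quantiles of responder data are therefore confounded
by nonresponse, and guidelines built on them can misprescribe.

`nradjust` implements the full analysis pipeline for this setting, for
biostatisticians and surgical-outcomes researchers:

* **Cohort assembly** — eligibility filters, MME conversion, and the
  known-zero rule: patients with no opioid prescription in the EHR have
  consumption measured as exactly zero, raising the measurement rate well
  above the survey response rate.
* **Imputation** — generalized low-rank model (GLRM) completion of missing
  predictors plus non-collinear missingness indicators.
* **Diagnostics** — binned chi-squared tests of response/measurement against
  each covariate (Yates-corrected for 2×2), Kolmogorov–Smirnov checks on raw
  continuous covariates, temporal rate series.
* **Stacked ensembles** — a cross-validated Super Learner (outcome mean,
  stratification on prescribed/discharge-day MMEs, OLS, lasso, random
  forest; each non-trivial learner with all predictors and with predictors
  screened at correlation p < 0.1) with exact simplex-weight optimization.
* **Targeted double-robust quantile estimation** — the core estimator (see
  below).
* **Variable importance** — random-forest screening plus tree-split-count
  rankings for response and for consumption; variables high in both lists
  are flagged as observed confounders.
* **Reporting** — adjusted-vs-unadjusted correction summaries, comparison to
  a reference survey, prescription-vs-consumption gaps, rolling quantile
  trends.
* **Synthetic cohorts** — a generator calibrated to the marginal structure
  of a real single-institution cohort (29% unprescribed, 20.5% response,
  informative nonresponse), with ground-truth quantile oracles for
  validation.

## The estimator

Let `Y` be consumed MMEs, `W` the EHR covariates, and `M` the indicator that
consumption was measured (survey response, or a documented zero
prescription). Assuming measurement is ignorable given `W` (MAR), each point
of the distribution function `F(y) = P(Y ≤ y)` is estimated by targeted
maximum likelihood:

1. **Propensity**: `g(W) = P(M = 1 | W)` by a stacked ensemble, truncated to
   `[0.01, 1]`.
2. **Outcome regressions**: for each threshold `y_j` in a grid,
   `Q_j(W) = P(Y ≤ y_j | W)` by an ensemble fit among measured records.
3. **Targeting**: a one-dimensional logistic fluctuation with clever
   covariate `H = M / g(W)` solves, per threshold, the efficient
   influence-curve equation; the targeted marginal is
   `F̂(y_j) = mean_i expit(logit Q_j(W_i) + ε_j / g(W_i))`, monotonized by
   isotonic regression.

Quantiles are left-continuous generalized inverses of `F̂`; 95% confidence
intervals invert the pointwise Wald band built from the influence curve
`IC_j = (M/g)(1(Y ≤ y_j) − Q*_j) + Q*_j − F̂(y_j)`. The estimator is double
robust: consistent if either `g` or the `Q_j` are consistently estimated.

## Worked example

```r
library(nradjust)

params <- cohort_params(n_patients = 6553, seed = 7)   # study-sized cohort
cohort <- generate_cohort(params)
mean(cohort$responded)   # 0.201  -- survey response
mean(cohort$measured)    # 0.432  -- measured incl. EHR-documented zeros

one <- cohort[cohort$procedure_group == "spinal fusion/laminectomy", ]
res <- adjust_quantiles(one, levels = c(0.5, 0.75),
  propensity_library = list(lrn_mean(), lrn_strat(), lrn_glm("all"), lrn_glm("cor_p")),
  cdf_library = list(lrn_mean(), lrn_strat(), lrn_glm("all")),
  folds = 5, seed = 7, procedure_group = "spinal fusion/laminectomy")
res$estimates
#>             procedure_group level     method  point  ci_low ci_high n_total n_measured
#> 1 spinal fusion/laminectomy  0.50   adjusted  50.84  13.723   95.71     739        164
#> 2 spinal fusion/laminectomy  0.75   adjusted 227.42 170.478  294.96     739        164
#> 3 spinal fusion/laminectomy  0.50 unadjusted  38.35   5.502   89.25     164        164
#> 4 spinal fusion/laminectomy  0.75 unadjusted 207.59 154.312  301.96     164        164
```

The adjusted median (50.8 MMEs) sits 33% above the naive responder median
(38.4 MMEs): responders in this cohort over-represent low consumers, so the
unadjusted survey would understate typical consumption — exactly the failure
a consumption-informed guideline needs protecting from. The importance
module shows why the correction is identifiable:

```r
imp <- importance_analysis(cohort, seed = 7)
head(imp$measurement, 3)
#>      variable  share rank
#> 1        race 0.2029    1
#> 2   age_years 0.1666    2
#> 3 tobacco_use 0.1487    3
imp$confounders
#> [1] "age_years"      "tobacco_use"    "prescribed_mme"
```

Age and tobacco use predict *both* measurement and consumption — observed
confounding, hence correctable nonresponse bias.

The whole pipeline (simulate → assemble → impute → diagnose → estimate →
importance → report) also runs from one call:

```r
run_pipeline("all", config = NULL, outdir = "run1", seed = 1)
```

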