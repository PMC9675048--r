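---
title: "Targeted nonresponse adjustment of consumption quantiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted nonresponse adjustment of consumption quantiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nradjust)
```

## The estimation problem

A post-surgical cohort is surveyed by SMS-to-web about opioid consumption
after discharge. For each patient we observe EHR covariates $W$, a
measurement indicator $M$ (the survey was answered, or the EHR documents no
opioid prescription so consumption is a known zero), and — when $M = 1$ —
consumed morphine milligram equivalents $Y$. The estimands are quantiles
(median, 75th percentile) of $Y$ per surgical procedure, the quantities that
consumption-informed prescribing guidelines use.

Only about a fifth of patients respond, and response is informative: in both
real cohorts and this package's generator, age, tobacco use and in-hospital
opioid dose shift response *and* consumption. The empirical quantile of
responder data is therefore inconsistent for the population quantile.

## The targeted estimator

We assume measurement is ignorable given covariates, $Y \perp M \mid W$
(MAR), with positivity $g(W) = P(M=1\mid W) > 0$. The distribution function
$F(y) = E[P(Y \le y \mid W)]$ is estimated pointwise over a grid
$y_1 < \dots < y_m$ by targeted maximum likelihood:

1. an ensemble propensity $\hat g(W)$, truncated to $[g_{\min}, 1]$;
2. ensemble regressions $\hat Q_j(W) \approx P(Y \le y_j \mid W)$ fit among
   measured records;
3. a one-parameter logistic fluctuation per threshold with clever covariate
   $H = M/\hat g(W)$: $\varepsilon_j$ maximizes the Bernoulli likelihood of
   $Z_j = 1(Y \le y_j)$ against offset
   $\operatorname{logit}\hat Q_j + \varepsilon H$ among measured records,
   and $\hat F(y_j) = \frac1n\sum_i
   \operatorname{expit}(\operatorname{logit}\hat Q_j(W_i) + \varepsilon_j/\hat g(W_i))$.

The fluctuation solves the efficient influence-curve equation
$\frac1n\sum_i (M_i/\hat g_i)(Z_{ij} - Q^*_{ij}) = 0$, which makes the
estimator double robust — consistent if either $\hat g$ or $\hat Q_j$ is —
and asymptotically efficient when both are. Quantiles are left-continuous
generalized inverses of the monotonized $\hat F$; confidence intervals
invert the pointwise 95% Wald band with
$\widehat{se}_j = \sqrt{\widehat{\operatorname{var}}(IC_j)/n}$. Inverting the
band avoids estimating the density of $Y$ at the quantile, which a
delta-method interval would require.

The published methodology this reproduces describes the three components
(inverse-probability weights, outcome regression, parameter-specific
targeting) without committing to equations; per-threshold
CDF-targeting-then-inversion is the standard TMLE construction for
distribution functions and is the declared design choice here. Each
$\varepsilon_j$ is retained in the fitted object for audit. When the Newton
solve for $\varepsilon_j$ fails (flat likelihood, extreme offsets), a
weighted-intercept update (weights $1/\hat g$) solving the same score
equation is substituted and logged.

## Parameters that matter

* **Grid** (`grid_max`, default 201): unique observed consumption values
  when there are at most 201 of them (consumption is pill-discrete, so this
  is usually exact), else 201 type-1 quantile knots; 0 is always included.
  Coarse grids bias the generalized inverse upward by up to one knot
  spacing; the acceptance tolerances carry an explicit 0.25-MME allowance
  for this.
* **Propensity truncation** (`bounds`, default `[0.01, 1]`): caps weights at
  100. The source analysis is silent; untruncated weights make the
  fluctuation unstable at realistic response rates.
* **Folds** (`folds`, default 10): cross-validation folds for both nuisance
  ensembles, stratified by class for binary tasks. The cited ensemble
  software defaults to 10; nothing in the method requires it.
* **Estimand population** (`population`, default `"prescribed"`): the
  outcome regressions are fit among prescribed patients, so the natural
  estimand is consumption given a nonzero prescription. The `"all"` option
  mixes a point mass at zero with weight equal to the unprescribed fraction
  (those zeros are known exactly, not estimated), scaling the standard
  errors by the prescribed fraction. The source publication does not state
  which population its per-procedure figures use; both are provided, neither
  asserted.
* **Meta-learner**: continuous tasks solve the simplex-constrained least
  squares exactly (quadprog), with the best single learner always among the
  candidates; binary tasks minimize log-loss by projected gradient started
  at the best single learner with monotone backtracking. Both constructions
  guarantee the stacked cross-validated risk never exceeds any single
  learner's.
* **Cross-fitting** of nuisances is off by default (the source analysis does
  not mention it); the ensemble's internal cross-validation governs only the
  weights.

## The learner libraries

The continuous library has 8 entries: outcome mean; stratification on
prescribed-MME bins {0, 1–99, 100–299, 300+} × discharge-day-MME bins
{0, 1–10, >10} (the only binning printed in the source tables, with empty
strata falling back to the grand mean); OLS, lasso and random forest, each
with all predictors and with predictors screened by Pearson-correlation
p < 0.1. The binary (propensity) library would add BART with both screens
(10 entries); no sum-of-trees backend exists in this build's environment, so
the library degrades to the same 8 entries with a logged notice — the
stacking contract is library-agnostic and no acceptance property depends on
BART. The random forest is a deterministic bagged-CART engine compiled in
`src/`, which also exposes the per-variable split counts the importance
module needs.

Screening is recomputed inside each training fold; if no predictor passes,
the single smallest-p predictor is kept so the design is never empty.

## What the synthetic generator does and does not emulate

The generator is calibrated to the marginal structure of a real
single-institution cohort: 29.1% of patients with no opioid prescription
(measured zeros), overall response ≈ 20.5% (logistic intercept −1.3976
calibrated by large-sample simulation under the default coefficients),
response log-odds shifted by age bin, race, tobacco, alcohol, ASA class,
length of stay, preoperative-assessment presence and discharge-day dose with
directions and spans (≈12–28% across strata) matching the published
bivariate table, and a preoperative-assessment block (tobacco + alcohol)
missing together for 13.5% of patients.

Consumption is `prescribed_mme × B` with `B` a zero-inflated Beta fraction
(precision 2.5) whose mean and zero-probability depend on age bin, tobacco
and discharge-day-dose bin. This guarantees the support constraint
`0 ≤ consumed ≤ prescribed`, right skew, and a point mass at zero. The
effect magnitudes are a design choice (the source reports no outcome model):
they are set so that the same covariates drive response and consumption
strongly enough to produce the double-digit relative corrections the source
study reports — under weak confounding the adjusted and naive estimators
would be indistinguishable and the double-robustness property untestable at
realistic Monte-Carlo sizes. Because all true effects act through *discrete*
bins, a saturated cell-mean learner is exactly correctly specified and a
main-effects logistic regression matches the true (additive-logistic)
propensity — this is what makes the two arms of the double-robustness
criterion implementable without approximation slack.

Not emulated: SMS delivery timing and reminders, free-text fields,
procedure-specific prescription-size distributions beyond a typical-MME
location per procedure, and any dependence of prescription probability on
procedure (so synthetic per-procedure cohorts all contain ≈29% unprescribed
patients, unlike, say, real sternotomy cohorts). A green simulation
therefore establishes estimator correctness under the stated DGP, not
fidelity of any particular procedure's consumption distribution.

`true_quantile()` is the oracle: a one-million-draw Monte-Carlo quantile of
the latent consumption distribution, independent of the response mechanism.

## Numerical choices

* GLRM: quadratic loss on per-column standardized entries for all column
  kinds (the source cites the GLRM framework without stating per-type
  losses; quadratic is the simplest member and adequate for
  indicator-encoded data), alternating ridge least squares grouped by
  missingness pattern, convergence at relative objective change `1e-6`, max
  500 sweeps, objective asserted non-increasing. Default rank 5. Indicator
  columns are clipped to [0, 1] after imputation.
* Missingness-indicator collinearity is *exact* pattern identity (the
  "perfect" case); near-collinear indicators are kept.
* Chi-squared tests use Yates continuity correction iff the table is 2×2 —
  the convention that reproduces the published sex-row p-value (0.146) from
  reconstructed counts; larger tables use uncorrected Pearson. Records
  missing a covariate are dropped from that covariate's test only.
* Unadjusted quantiles are type-1 (inverted ECDF) with order-statistic
  (binomial) confidence intervals.
* The quantile inversion applies a `1e-9` floating-point guard at exact
  ties of `F̂` with the level.
* Tie-breaking in the meta-learner favors earlier library order (the best
  single learner is chosen by `which.min`).
* Importance tallies use many shallow trees (depth ≤ 2, minimum node 50,
  500 trees) — the regime of a sum-of-trees sampler's prior. Deep tallying
  trees inflate split counts of continuous noise variables after signal is
  exhausted, which is a property of count-based importance, not of the data.
  Categorical variables are screened and tallied whole (integer-coded before
  indicator expansion), and indicator splits aggregate back to the parent
  variable by the design matrix's recorded parent mapping.

## Known limitations

* Identification rests on MAR given the measured covariates; confounding by
  unrecorded determinants of response and consumption is not corrected.
* The confidence band inversion yields asymmetric, sometimes conservative
  intervals near flat regions of `F̂` (e.g. just above the zero mass);
  empirical coverage of the true median in the well-specified simulation is
  ≈94% at n = 5000.
* Single imputation: imputation uncertainty is not propagated (the source
  analysis also imputes once).
* The consumed-MME computation assumes `consumed = prescribed − remaining`;
  whether the source used dispensed or prescribed counts when
  pills-remaining was reported is not stated.
* No BART backend: propensity libraries run with 8 entries, and importance
  tallies come from the random forest; both facts are recorded in the run
  artifacts.
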