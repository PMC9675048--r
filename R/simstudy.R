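#' Simulation designs for validating the double-robust estimator
#'
#' `dr_params()` builds a cohort parameterization in which survey response
#' depends only on three discrete covariates (age bin, tobacco use,
#' discharge-day MME bin) — the same covariates that shift consumption. The
#' true propensity is then additive-logistic in the bin indicators (so a
#' main-effects logistic regression is correctly specified) and the true
#' conditional outcome distribution is a function of the 48 covariate cells
#' (so a saturated cell-mean learner is correctly specified). This makes the
#' two arms of the double-robustness property testable exactly:
#' a correct propensity with a null (mean-only) outcome model, and a correct
#' outcome model with a misspecified-constant propensity.
#'
#' @param n_patients cohort size.
#' @param seed root seed.
#' @return A [cohort_params()] object.
#' @export
dr_params <- function(n_patients = 20000L, seed = 1L) {
  rc <- default_response_coefficients()
  cohort_params(
    n_patients = n_patients,
    response_coefficients = rc[c("age_bin", "tobacco_use", "ddmme_bin")],
    seed = seed)
}

# indicator design over the discrete response drivers (reference levels
# dropped); the saturated cell structure is recoverable from these columns
discrete_design <- function(records) {
  rec <- derive_bins(records)
  cols <- list()
  for (v in c("age_bin", "tobacco_use", "ddmme_bin")) {
    lev <- if (is.factor(rec[[v]])) levels(rec[[v]]) else sort(unique(rec[[v]]))
    for (l in lev[-1])
      cols[[paste0(v, "=", l)]] <- as.numeric(rec[[v]] == l)
  }
  do.call(cbind, cols)
}

#' One replicate of the double-robustness / coverage simulation
#'
#' Generates a cohort from `params`, restricts to prescribed patients, and
#' runs the targeted estimator with the nuisance configuration of the chosen
#' scenario:
#' * `"prop_correct"` — propensity by main-effects logistic regression
#'   (correct); outcome library mean-only (misspecified).
#' * `"outcome_correct"` — outcome by saturated cell means (correct);
#'   propensity constant (misspecified).
#' * `"both_correct"` — both correct (used for CI coverage).
#'
#' @param params from [dr_params()]; `params$seed` should vary by replicate.
#' @param scenario see above.
#' @param level quantile level.
#' @param grid_max grid cap (quantile knots).
#' @param folds cross-validation folds.
#' @return list: `adjusted` (point), `ci` (length-2), `naive` (responder
#'   empirical quantile), `n`.
#' @export
simulate_dr_once <- function(params,
                             scenario = c("prop_correct", "outcome_correct",
                                          "both_correct"),
                             level = 0.5, grid_max = 61L, folds = 5L) {
  scenario <- match.arg(scenario)
  rec <- generate_cohort(params)
  presc <- rec[rec$prescribed_mme > 0, , drop = FALSE]
  X <- discrete_design(presc)
  M <- presc$measured
  y <- presc$consumed_mme
  seed <- params$seed

  glm_lib <- list(lrn_glm("all"))
  cell_lib <- list(lrn_strat(cols = colnames(X), breaks = NULL, id = "cells"))
  mean_lib <- list(lrn_mean())
  prop_lib <- switch(scenario, prop_correct = glm_lib,
                     outcome_correct = mean_lib, both_correct = glm_lib)
  cdf_lib <- switch(scenario, prop_correct = mean_lib,
                    outcome_correct = cell_lib, both_correct = cell_lib)

  prop <- fit_propensity(X, M, library = prop_lib, bounds = c(0.01, 1),
                         folds = folds, seed = seed)
  grid <- cdf_grid(y[M == 1], grid_max)
  fits <- fit_threshold_regressions(X, y, M, grid, library = cdf_lib,
                                    folds = folds, seed = seed)
  tc <- target_cdf(fits, prop)
  est <- invert_quantile(tc, level)
  list(adjusted = est$point, ci = c(est$ci_low, est$ci_high),
       naive = quantile_type1(y[M == 1], level), n = nrow(presc))
}
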