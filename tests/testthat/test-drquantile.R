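light_lib <- function() list(lrn_mean(), lrn_glm("all"))

test_that("propensity fitting honors truncation bounds", {
  set.seed(1)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  pf <- fit_propensity(X, rep(1L, 200), library = list(lrn_mean()), folds = 5)
  expect_true(all(pf$g > 0.999))

  expect_error(fit_propensity(X, rep(1L, 200), bounds = c(0, 1)), "bounds")
  expect_error(fit_propensity(X, rep(1L, 200), bounds = c(0.5, 0.2)), "bounds")

  set.seed(2)
  n <- 5000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  truep <- plogis(-1 + X[, 1])
  M <- rbinom(n, 1, truep)
  pf <- fit_propensity(X, M, library = light_lib(), folds = 5, seed = 2)
  expect_gt(cor(pf$g, truep), 0.8)
  expect_true(all(1 / pf$g <= 100))  # bounds [0.01, 1]
})

test_that("threshold regressions recover the marginal CDF under MCAR", {
  set.seed(3)
  n <- 3000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(NA_real_, n)
  M <- rbinom(n, 1, 0.5)
  y[M == 1] <- rgamma(sum(M), 2, 0.1)
  grid <- cdf_grid(y[M == 1], 41)
  fits <- fit_threshold_regressions(X, y, M, grid, library = light_lib(),
                                    folds = 5, seed = 3)
  expect_equal(fits$F_init[length(grid)], 1)  # grid top >= max(Y)
  ecdf_m <- vapply(grid, function(g) mean(y[M == 1] <= g), numeric(1))
  expect_lt(max(abs(fits$F_init - ecdf_m)), 0.03)
  expect_error(fit_threshold_regressions(X, y, M, c(-1, 0, 10)), "grid")
})

test_that("with full response the targeted CDF is the empirical CDF", {
  rec <- generate_cohort(full_response_params(n = 500, seed = 4))
  presc <- rec[rec$prescribed_mme > 0, ]
  X <- discrete_design(presc)
  y <- presc$consumed_mme
  M <- presc$measured
  expect_true(all(M == 1))
  prop <- fit_propensity(X, M, library = list(lrn_mean()), folds = 5)
  grid <- cdf_grid(y, 201)
  fits <- fit_threshold_regressions(X, y, M, grid, library = light_lib(),
                                    folds = 5, seed = 4)
  tc <- target_cdf(fits, prop)
  ecdfv <- vapply(grid, function(g) mean(y <= g), numeric(1))
  expect_lt(max(abs(tc$F - ecdfv)), 1e-6)
  for (lv in c(0.5, 0.75))
    expect_equal(invert_quantile(tc, lv)$point, quantile(y, lv, type = 1),
                 ignore_attr = TRUE)
})

test_that("the influence curve has mean zero at every threshold", {
  p <- dr_params(3000L, seed = 5)
  rec <- generate_cohort(p)
  presc <- rec[rec$prescribed_mme > 0, ]
  X <- discrete_design(presc)
  prop <- fit_propensity(X, presc$measured, library = light_lib(), folds = 5,
                         seed = 5)
  grid <- cdf_grid(presc$consumed_mme[presc$measured == 1], 31)
  fits <- fit_threshold_regressions(X, presc$consumed_mme, presc$measured,
                                    grid, library = list(lrn_mean()),
                                    folds = 5, seed = 5)
  tc <- target_cdf(fits, prop)
  expect_lt(max(abs(colMeans(tc$IC))), 1e-8)
  expect_true(all(diff(tc$F) >= 0))
  expect_true(all(tc$F >= 0 & tc$F <= 1))
})

test_that("quantile inversion follows the generalized-inverse convention", {
  tc <- structure(list(grid = c(0, 10, 30, 50),
                       F = c(0, 0, 1, 1), se = rep(0, 4),
                       n = 100, n_measured = 100), class = "targeted_cdf")
  for (lv in c(0.1, 0.5, 0.9))
    expect_equal(invert_quantile(tc, lv)$point, 30)
  q50 <- invert_quantile(tc, 0.5); q75 <- invert_quantile(tc, 0.75)
  expect_gte(q75$point, q50$point)
  expect_true(q50$ci_low <= q50$point && q50$point <= q50$ci_high)
  tc$F <- c(0, 0, 0.4, 0.4)
  expect_error(invert_quantile(tc, 0.5), "grid too short")
  expect_error(invert_quantile(tc, 1.5), "level")
})

test_that("unadjusted quantiles use the inverted-ECDF convention", {
  expect_equal(unadjusted_quantile(c(0, 0, 0, 10), 0.5)$point, 0)
  expect_equal(unadjusted_quantile(rep(7, 5), 0.2)$point, 7)
  expect_equal(unadjusted_quantile(rep(7, 5), 0.9)$point, 7)
  q <- unadjusted_quantile(rgamma(200, 2), 0.5)
  expect_true(q$ci_low <= q$point && q$point <= q$ci_high)
  expect_error(unadjusted_quantile(numeric(0), 0.5), "no measured")
})

test_that("under MCAR response adjusted and unadjusted agree", {
  p <- cohort_params(n_patients = 6000, seed = 6,
                     response_coefficients = list(),
                     response_intercept = qlogis(0.4))
  rec <- generate_cohort(p)
  presc <- rec[rec$prescribed_mme > 0, ]
  X <- discrete_design(presc)
  prop <- fit_propensity(X, presc$measured, library = light_lib(), folds = 5,
                         seed = 6)
  grid <- cdf_grid(presc$consumed_mme[presc$measured == 1], 101)
  fits <- fit_threshold_regressions(X, presc$consumed_mme, presc$measured,
                                    grid, library = light_lib(), folds = 5,
                                    seed = 6)
  tc <- target_cdf(fits, prop)
  adj <- invert_quantile(tc, 0.5)
  una <- unadjusted_quantile(presc$consumed_mme[presc$measured == 1], 0.5)
  expect_gte(adj$point, una$ci_low)
  expect_lte(adj$point, una$ci_high)
})

test_that("single-group pipeline with universal response is exact", {
  rec <- generate_cohort(full_response_params(n = 300, seed = 7))
  rec$procedure_group <- "only"
  res <- adjust_quantiles(rec, levels = c(0.5, 0.75),
                          propensity_library = list(lrn_mean()),
                          cdf_library = light_lib(), folds = 5, seed = 7)
  ym <- rec$consumed_mme[rec$prescribed_mme > 0]
  for (lv in c(0.5, 0.75)) {
    a <- res$estimates[res$estimates$level == lv, ]
    expect_equal(a$point[a$method == "adjusted"],
                 quantile(ym, lv, type = 1), ignore_attr = TRUE)
    expect_equal(a$point[a$method == "adjusted"],
                 a$point[a$method == "unadjusted"])
  }
})

test_that("the all-patients estimand mixes in the known zeros", {
  rec <- generate_cohort(full_response_params(n = 800, seed = 8))
  res_p <- adjust_quantiles(rec, levels = 0.75, population = "prescribed",
                            propensity_library = list(lrn_mean()),
                            cdf_library = list(lrn_mean()), folds = 5,
                            grid_max = 2000L, seed = 8)
  res_a <- adjust_quantiles(rec, levels = 0.75, population = "all",
                            propensity_library = list(lrn_mean()),
                            cdf_library = list(lrn_mean()), folds = 5,
                            grid_max = 2000L, seed = 8)
  adj_p <- res_p$estimates[res_p$estimates$method == "adjusted", ]
  adj_a <- res_a$estimates[res_a$estimates$method == "adjusted", ]
  expect_lte(adj_a$point, adj_p$point)  # zero mass shifts quantiles down
  expect_equal(adj_a$n_total, nrow(rec))
  ally <- rec$consumed_mme
  expect_equal(adj_a$point, quantile(ally, 0.75, type = 1), ignore_attr = TRUE)
})

test_that("small groups are skipped with a notice", {
  rec <- generate_cohort(full_response_params(n = 200, seed = 9))
  rec$procedure_group <- c(rep("big", 195), rep("tiny", 5))
  expect_message(
    est <- estimate_by_procedure(rec, levels = 0.5, min_n = 30,
                                 propensity_library = list(lrn_mean()),
                                 cdf_library = list(lrn_mean()), folds = 5,
                                 seed = 9),
    "tiny")
  expect_equal(attr(est, "skipped"), "tiny")
  expect_setequal(unique(est$procedure_group), "big")
})
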