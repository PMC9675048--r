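sim_task <- function(n = 300, d = 6, seed = 1, binary = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  eta <- X[, 1] - 0.5 * X[, 2]
  y <- if (binary) rbinom(n, 1, plogis(eta)) else eta + rnorm(n, sd = 0.5)
  list(X = X, y = y)
}

test_that("default libraries have the documented sizes", {
  expect_length(default_library("continuous"), 8)
  # no BART backend in this environment: binary library degrades with notice
  expect_message(lib <- default_library("binary"), "degrades")
  expect_length(lib, 8)
  ids <- vapply(default_library("continuous"), `[[`, "", "id")
  expect_setequal(ids, c("mean", "stratified", "glm_all", "glm_cor_p",
                         "lasso_all", "lasso_cor_p", "rf_all", "rf_cor_p"))
})

test_that("correlation screening keeps signal and never empties the design", {
  set.seed(2)
  n <- 500
  X <- matrix(rnorm(n * 10), n, 10)
  y <- 3 * X[, 1]  # noiseless signal in column 1 only
  keep <- screen_correlation(X, y, 0.1)
  expect_true(1 %in% keep)

  expect_length(screen_correlation(X, rnorm(n), 0.999), 10)

  yind <- rnorm(1000)
  Xn <- matrix(rnorm(1000 * 20), 1000, 20)
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    length(screen_correlation(matrix(rnorm(1000 * 20), 1000, 20), rnorm(1000), 0.1))
  }, numeric(1))
  expect_lt(abs(mean(kept) - 2), 1)  # null: ~ alpha * d columns pass

  Xc <- cbind(X, const = 1)
  expect_warning(screen_correlation(Xc, y, 0.1), "constant")
})

test_that("mean-only library collapses to the grand mean", {
  tk <- sim_task(seed = 3)
  m <- cv_stack(tk$X, tk$y, list(lrn_mean()), folds = 5, task = "continuous")
  expect_equal(m$weights, 1)
  expect_equal(predict_ensemble(m, tk$X), rep(mean(tk$y), nrow(tk$X)))
})

test_that("the true-model learner dominates noise learners", {
  tk <- sim_task(n = 2000, seed = 4)
  noise_lrn <- function(k) new_learner(paste0("noise", k), function(X, y, task, seed) {
    set.seed(seed); b <- rnorm(ncol(X))
    list(predict = function(Xnew) drop(Xnew %*% b))
  })
  m <- cv_stack(tk$X, tk$y, list(lrn_glm("all"), noise_lrn(1), noise_lrn(2)),
                folds = 5, task = "continuous", seed = 1)
  expect_gt(m$weights[1], 0.9)
})

test_that("duplicated learners leave the combined prediction unchanged", {
  tk <- sim_task(seed = 5)
  m1 <- cv_stack(tk$X, tk$y, list(lrn_mean(), lrn_glm("all")),
                 folds = 5, task = "continuous", seed = 2)
  m2 <- cv_stack(tk$X, tk$y, list(lrn_mean(), lrn_glm("all"), lrn_glm("all")),
                 folds = 5, task = "continuous", seed = 2)
  expect_equal(predict_ensemble(m1, tk$X), predict_ensemble(m2, tk$X),
               tolerance = 1e-6)
})

test_that("stacked out-of-fold risk never exceeds any single learner", {
  for (s in 1:3) {
    tk <- sim_task(n = 400, seed = 10 + s, binary = (s == 2))
    task <- if (s == 2) "binary" else "continuous"
    lib <- list(lrn_mean(), lrn_strat(cols = "x1", breaks = list(c(-Inf, 0, Inf))),
                lrn_glm("all"), lrn_glm("cor_p"))
    m <- cv_stack(tk$X, tk$y, lib, folds = 5, task = task, seed = s)
    expect_lte(m$stack_risk, min(m$cv_risks) + 1e-8)
    expect_true(all(m$weights >= 0))
    expect_equal(sum(m$weights), 1, tolerance = 1e-8)
  }
})

test_that("predict_ensemble is a convex combination with column checks", {
  tk <- sim_task(seed = 6)
  m <- cv_stack(tk$X, tk$y, list(lrn_mean(), lrn_glm("all")), folds = 5,
                task = "continuous", seed = 3)
  preds <- vapply(seq_along(m$fits), function(j)
    m$fits[[j]]$predict(tk$X[, m$screen_sets[[j]], drop = FALSE]),
    numeric(nrow(tk$X)))
  ens <- predict_ensemble(m, tk$X)
  expect_true(all(ens >= apply(preds, 1, min) - 1e-9))
  expect_true(all(ens <= apply(preds, 1, max) + 1e-9))
  expect_error(predict_ensemble(m, tk$X[, 1:3]), "x4")
})

test_that("stratified learner reproduces brute-force stratum means", {
  rec <- generate_cohort(tiny_params(n = 1500, seed = 16))
  presc <- rec[rec$measured == 1 & rec$prescribed_mme > 0, ]
  X <- cbind(prescribed_mme = presc$prescribed_mme,
             discharge_day_mme = presc$discharge_day_mme)
  y <- presc$consumed_mme
  fit <- lrn_strat()$fit(X, y, "continuous", 1)
  pred <- fit$predict(X)
  b <- derive_bins(presc)
  key <- paste(b$rx_bin, b$ddmme_bin)
  oracle <- tapply(y, key, mean)[key]
  expect_equal(pred, as.vector(oracle))

  # stratum empty in training (zero-prescription bin) falls back to grand mean
  Xnew <- cbind(prescribed_mme = 0.5, discharge_day_mme = 15)
  expect_equal(fit$predict(Xnew), mean(y))
})

test_that("binary folds are class-stratified and rare-class tasks run", {
  set.seed(7)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep(1, 15), rep(0, 285))
  m <- cv_stack(X, y, list(lrn_mean(), lrn_glm("all")), folds = 10,
                task = "binary", seed = 4)
  for (v in unique(m$fold))
    expect_gt(sum(y[m$fold == v]), 0)  # every fold carries both classes
  expect_true(all(predict_ensemble(m, X) > 0 & predict_ensemble(m, X) < 1))
})

test_that("ensemble manifest serializes the audit fields", {
  tk <- sim_task(seed = 8)
  m <- cv_stack(tk$X, tk$y, list(lrn_mean(), lrn_glm("all")), folds = 5,
                task = "continuous", seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  ensemble_manifest(m, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$learners, m$learner_ids)
  expect_equal(sum(j$weights), 1, tolerance = 1e-8)
})
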