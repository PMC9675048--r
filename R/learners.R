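#' Base learners for the stacked ensemble
#'
#' Constructors for the members of the ensemble library. Each learner is a
#' `list(id, screen, fit)` where `fit(X, y, task, seed)` returns an object
#' with a `$predict(Xnew)` closure. `screen` is `"all"` (use every predictor)
#' or `"cor_p"` (restrict to predictors whose Pearson correlation with the
#' outcome has p < `alpha`, see [screen_correlation()]). Screening is applied
#' inside cross-validation on the training folds.
#'
#' * `lrn_mean()` — the outcome mean (the null benchmark).
#' * `lrn_strat()` — stratification on binned prescribed MMEs and
#'   discharge-day MMEs (or any configured columns); predicts the training
#'   stratum mean, falling back to the grand mean for empty strata.
#' * `lrn_glm()` — OLS for continuous tasks, logistic regression for binary.
#' * `lrn_lasso()` — glmnet lasso with internally cross-validated lambda.
#' * `lrn_rf()` — the package's deterministic bagged CART forest.
#' * `new_learner()` — wrap any custom `fit(X, y, task, seed)` function
#'   (used in simulations to include the true model in a library).
#'
#' @param screen `"all"` or `"cor_p"`.
#' @param alpha screening p-value threshold.
#' @param id learner label (unique within a library).
#' @name learners
NULL

#' @rdname learners
#' @param fit_fun function `(X, y, task, seed)` returning a list with a
#'   `predict` closure.
#' @export
new_learner <- function(id, fit_fun, screen = "all", alpha = 0.1) {
  stopifnot(is.character(id), is.function(fit_fun))
  structure(list(id = id, screen = screen, alpha = alpha, fit = fit_fun),
            class = "nr_learner")
}

#' @rdname learners
#' @export
lrn_mean <- function() {
  new_learner("mean", function(X, y, task, seed) {
    m <- mean(y)
    list(predict = function(Xnew) rep(m, nrow(Xnew)))
  })
}

#' @rdname learners
#' @param cols columns of the design matrix to stratify on.
#' @param breaks list of break vectors parallel to `cols`; `NULL` entries
#'   treat the column's values as already-discrete codes.
#' @export
lrn_strat <- function(cols = c("prescribed_mme", "discharge_day_mme"),
                      breaks = list(c(-Inf, 1, 100, 300, Inf),
                                    c(-Inf, 1, 11, Inf)),
                      id = "stratified") {
  force(cols); force(breaks)
  # integer-encoded stratum keys (left-closed bins, as elsewhere); unseen
  # levels/strata at prediction time fall back to the grand mean
  encode <- function(X, use, levels_list) {
    key <- numeric(nrow(X))
    for (i in seq_along(use)) {
      v <- X[, use[i]]
      br <- if (is.null(breaks)) NULL else breaks[[match(use[i], cols)]]
      code <- if (is.null(br)) match(v, levels_list[[i]])
              else findInterval(v, br)
      key <- key * (length(levels_list[[i]]) + length(br) + 2L) + code
    }
    key
  }
  new_learner(id, function(X, y, task, seed) {
    use <- intersect(cols, colnames(X))
    levels_list <- lapply(use, function(cl) sort(unique(X[, cl])))
    if (!length(use)) {
      grand <- mean(y)
      return(list(predict = function(Xnew) rep(grand, nrow(Xnew))))
    }
    key <- encode(X, use, levels_list)
    sums <- rowsum(y, key)
    counts <- rowsum(rep(1, length(y)), key)
    key_levels <- as.numeric(rownames(sums))
    means <- as.vector(sums) / as.vector(counts)
    grand <- mean(y)
    list(predict = function(Xnew) {
      m <- means[match(encode(Xnew, use, levels_list), key_levels)]
      m[is.na(m)] <- grand
      m
    })
  })
}

#' @rdname learners
#' @export
lrn_glm <- function(screen = "all", alpha = 0.1,
                    id = paste0("glm_", screen)) {
  new_learner(id, function(X, y, task, seed) {
    Xi <- cbind(`(Intercept)` = 1, X)
    if (task == "binary") {
      fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
      beta <- coef(fit)
    } else {
      beta <- lm.fit(Xi, y)$coefficients
    }
    beta[is.na(beta)] <- 0
    list(predict = function(Xnew) {
      eta <- drop(cbind(1, Xnew[, colnames(X), drop = FALSE]) %*% beta)
      if (task == "binary") plogis(eta) else eta
    })
  }, screen = screen, alpha = alpha)
}

#' @rdname learners
#' @export
lrn_lasso <- function(screen = "all", alpha = 0.1,
                      id = paste0("lasso_", screen)) {
  new_learner(id, function(X, y, task, seed) {
    if (ncol(X) < 2 || nrow(X) < 20) {
      # glmnet needs >= 2 predictors; degrade to glm
      return(lrn_glm()$fit(X, y, task, seed))
    }
    fam <- if (task == "binary") "binomial" else "gaussian"
    set.seed(seed)
    foldid <- sample(rep_len(1:5, nrow(X)))
    cv <- glmnet::cv.glmnet(X, y, family = fam, foldid = foldid,
                            standardize = TRUE)
    list(predict = function(Xnew) {
      p <- predict(cv, newx = Xnew[, colnames(X), drop = FALSE],
                   s = "lambda.min",
                   type = if (task == "binary") "response" else "link")
      drop(p)
    })
  }, screen = screen, alpha = alpha)
}

#' @rdname learners
#' @param ntree,mtry,min_node,max_depth forest hyperparameters
#'   (`mtry = NULL` uses `max(1, floor(d/3))`).
#' @export
lrn_rf <- function(screen = "all", alpha = 0.1, ntree = 200L, mtry = NULL,
                   min_node = 5L, max_depth = 25L,
                   id = paste0("rf_", screen)) {
  new_learner(id, function(X, y, task, seed) {
    m <- mtry %||% max(1L, floor(ncol(X) / 3))
    fit <- .rf_fit_cpp(X, y, as.integer(ntree), as.integer(m),
                       as.integer(min_node), as.integer(max_depth),
                       1.0, TRUE, as.integer(seed %% 2147483647))
    cn <- colnames(X)
    list(predict = function(Xnew) {
      p <- .rf_predict_cpp(fit$trees, Xnew[, cn, drop = FALSE])
      if (task == "binary") clip(p, 0, 1) else p
    }, forest = fit, columns = cn)
  }, screen = screen, alpha = alpha)
}

has_bart_backend <- function() {
  # a faithful sum-of-trees backfitting sampler is not available in this
  # environment; the library degrades per the stacking contract
  FALSE
}

#' Default ensemble libraries
#'
#' The continuous (outcome-regression) library contains the outcome mean,
#' stratification on prescribed and discharge-day MMEs, OLS, lasso and random
#' forest — the last three each with all predictors and with
#' correlation-screened predictors (8 entries). The binary (propensity)
#' library adds BART with both screens when a sum-of-trees backend is
#' available; in this build no backend exists, so the binary library degrades
#' to the same 8 entries with a logged notice.
#'
#' @param task `"continuous"` or `"binary"`.
#' @return list of learners.
#' @export
default_library <- function(task = c("continuous", "binary")) {
  task <- match.arg(task)
  lib <- list(lrn_mean(), lrn_strat(),
              lrn_glm("all"), lrn_glm("cor_p"),
              lrn_lasso("all"), lrn_lasso("cor_p"),
              lrn_rf("all"), lrn_rf("cor_p"))
  if (task == "binary") {
    if (has_bart_backend()) {
      # would append bart_all / bart_cor_p here
    } else {
      message("no BART backend available; binary library degrades to 8 entries")
    }
  }
  lib
}
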