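#' Correlation-based predictor screening
#'
#' Retains the columns of `X` whose Pearson correlation with `y` is
#' significant at `alpha` (two-sided test). Constant columns are excluded
#' with a warning (their correlation is undefined). If no column passes, the
#' single smallest-p column is retained so the design is never empty.
#'
#' @param X complete numeric matrix.
#' @param y outcome vector.
#' @param alpha p-value threshold in (0, 1).
#' @return Integer vector of retained column indices.
#' @export
screen_correlation <- function(X, y, alpha = 0.1) {
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must be in (0, 1)")
  sds <- apply(X, 2, sd)
  const <- sds < 1e-12
  if (any(const))
    warning(sprintf("excluding %d constant column(s) from screening",
                    sum(const)))
  p <- rep(NA_real_, ncol(X))
  for (j in which(!const))
    p[j] <- suppressWarnings(cor.test(X[, j], y)$p.value)
  pass <- which(!is.na(p) & p < alpha)
  if (!length(pass)) pass <- which.min(p)
  pass
}

loss_of <- function(pred, y, task) {
  if (task == "binary") {
    p <- clip(pred, 1e-6, 1 - 1e-6)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else mean((y - pred)^2)
}

# Euclidean projection onto the probability simplex (Duchi et al. 2008)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# simplex weights minimizing squared error, solved exactly by QP; the best
# single learner is always a candidate so the stacked risk can never exceed it
solve_weights_gaussian <- function(Z, y) {
  L <- ncol(Z)
  D <- crossprod(Z) + diag(1e-8, L)
  dvec <- crossprod(Z, y)
  A <- cbind(rep(1, L), diag(L))
  sol <- tryCatch(
    quadprog::solve.QP(D, dvec, A, c(1, rep(0, L)), meq = 1)$solution,
    error = function(e) NULL)
  cand <- list()
  if (!is.null(sol)) cand <- c(cand, list(pmax(sol, 0) / sum(pmax(sol, 0))))
  for (j in seq_len(L)) {
    w <- numeric(L); w[j] <- 1; cand <- c(cand, list(w))
  }
  risks <- vapply(cand, function(w) mean((y - drop(Z %*% w))^2), numeric(1))
  cand[[which.min(risks)]]
}

# simplex weights minimizing Bernoulli log-loss by monotone projected
# gradient, initialized at the best single learner
solve_weights_binary <- function(Z, y, iter = 300L) {
  L <- ncol(Z)
  risks1 <- vapply(seq_len(L), function(j) loss_of(Z[, j], y, "binary"),
                   numeric(1))
  w <- numeric(L); w[which.min(risks1)] <- 1
  cur <- loss_of(drop(Z %*% w), y, "binary")
  step <- 1
  for (it in seq_len(iter)) {
    p <- clip(drop(Z %*% w), 1e-6, 1 - 1e-6)
    g <- drop(crossprod(Z, (p - y) / (p * (1 - p)))) / length(y)
    improved <- FALSE
    for (k in 1:20) {
      w2 <- project_simplex(w - step * g)
      new <- loss_of(drop(Z %*% w2), y, "binary")
      if (new < cur - 1e-12) { w <- w2; cur <- new; improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    step <- step * 2
  }
  w
}

make_folds <- function(y, V, task, seed) {
  set.seed(substream_seed(seed, "folds"))
  n <- length(y)
  fold <- integer(n)
  if (task == "binary") {
    # stratified by class so no fold sees a single outcome class
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(V), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(V), n))
  }
  fold
}

#' Cross-validated stacked ensemble (Super Learner)
#'
#' Fits every learner in the library on each of `V` training folds, assembles
#' the out-of-fold prediction matrix, and solves for convex (simplex) weights
#' minimizing the cross-validated risk — squared error for continuous tasks,
#' Bernoulli log-likelihood for binary tasks. The weighted combination's
#' cross-validated risk never exceeds the best single learner's (the best
#' single learner is the optimizer's starting point / a candidate). Base
#' learners are then refit on the full data. Deterministic given `seed`.
#'
#' @param X complete numeric matrix (no missing entries) with column names.
#' @param y outcome: numeric (continuous task) or 0/1 (binary task).
#' @param library list of learners (see [learners]); default by task.
#' @param folds number of cross-validation folds.
#' @param task `"continuous"` or `"binary"`.
#' @param seed integer seed.
#' @return An `ensemble_model`: weights, per-learner cross-validated risks,
#'   stacked risk, fold assignment, fitted full-data learners and their
#'   screen sets.
#' @export
cv_stack <- function(X, y, library = NULL, folds = 10L,
                     task = c("continuous", "binary"), seed = 1L) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete (impute first)", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (task == "binary" && !all(y %in% c(0, 1)))
    stop("binary task requires a 0/1 outcome", call. = FALSE)
  if (is.null(library)) library <- default_library(task)
  L <- length(library)
  n <- length(y)
  V <- min(folds, n)
  fold <- make_folds(y, V, task, seed)

  if (L == 1L) {
    # single-learner library: weights are trivially 1, no meta-learning step
    lrn <- library[[1]]
    cols <- if (identical(lrn$screen, "cor_p"))
      suppressWarnings(screen_correlation(X, y, lrn$alpha)) else seq_len(ncol(X))
    fit <- lrn$fit(X[, cols, drop = FALSE], y, task,
                   substream_seed(seed, "full_1"))
    pred <- fit$predict(X[, cols, drop = FALSE])
    risk <- loss_of(pred, y, task)
    return(structure(list(task = task, weights = 1,
                          learner_ids = lrn$id, cv_risks = risk,
                          stack_risk = risk, fold = fold, oof = NULL,
                          fits = list(fit), screen_sets = list(cols),
                          columns = colnames(X), seed = seed),
                     class = "ensemble_model"))
  }

  screen_cols <- function(lrn, Xtr, ytr) {
    if (identical(lrn$screen, "cor_p"))
      suppressWarnings(screen_correlation(Xtr, ytr, lrn$alpha))
    else seq_len(ncol(Xtr))
  }

  Z <- matrix(NA_real_, n, L)
  for (v in seq_len(V)) {
    tr <- fold != v; va <- !tr
    for (j in seq_len(L)) {
      lrn <- library[[j]]
      cols <- screen_cols(lrn, X[tr, , drop = FALSE], y[tr])
      fit <- lrn$fit(X[tr, cols, drop = FALSE], y[tr], task,
                     substream_seed(seed, paste0("fit", v, "_", j)))
      Z[va, j] <- fit$predict(X[va, cols, drop = FALSE])
    }
  }
  bad <- apply(Z, 2, function(z) any(!is.finite(z)))
  if (any(bad)) {
    warning(sprintf("non-finite out-of-fold predictions; forcing zero weight for: %s",
                    paste(vapply(library[bad], `[[`, "", "id"), collapse = ", ")))
    Z[, bad] <- mean(y)
  }
  risks <- vapply(seq_len(L), function(j) loss_of(Z[, j], y, task), numeric(1))
  w <- if (task == "binary") solve_weights_binary(Z, y)
       else solve_weights_gaussian(Z, y)
  if (any(bad)) { w[bad] <- 0; if (sum(w) > 0) w <- w / sum(w) }
  stack_risk <- loss_of(drop(Z %*% w), y, task)

  full_fits <- vector("list", L)
  full_cols <- vector("list", L)
  for (j in seq_len(L)) {
    lrn <- library[[j]]
    cols <- screen_cols(lrn, X, y)
    full_cols[[j]] <- cols
    full_fits[[j]] <- lrn$fit(X[, cols, drop = FALSE], y, task,
                              substream_seed(seed, paste0("full_", j)))
  }
  structure(list(task = task, weights = w,
                 learner_ids = vapply(library, `[[`, "", "id"),
                 cv_risks = risks, stack_risk = stack_risk,
                 fold = fold, oof = Z,
                 fits = full_fits, screen_sets = full_cols,
                 columns = colnames(X), seed = seed),
            class = "ensemble_model")
}

#' Predict from a stacked ensemble
#'
#' Convex combination of the base-learner predictions; binary-task outputs
#' are clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param model an `ensemble_model` from [cv_stack()].
#' @param X_new numeric matrix whose columns include the training columns.
#' @return numeric vector of predictions.
#' @export
predict_ensemble <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  missing_cols <- setdiff(model$columns, colnames(X_new))
  if (length(missing_cols))
    stop(sprintf("X_new lacks training column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  X_new <- X_new[, model$columns, drop = FALSE]
  out <- numeric(nrow(X_new))
  for (j in seq_along(model$fits)) {
    if (model$weights[j] == 0) next
    cols <- model$screen_sets[[j]]
    out <- out + model$weights[j] *
      model$fits[[j]]$predict(X_new[, cols, drop = FALSE])
  }
  if (model$task == "binary") out <- clip(out, 1e-6, 1 - 1e-6)
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> task=%s, %d learners\n", x$task,
              length(x$weights)))
  print(data.frame(learner = x$learner_ids, weight = round(x$weights, 4),
                   cv_risk = signif(x$cv_risks, 6)))
  cat(sprintf("stacked cv risk: %s\n", signif(x$stack_risk, 6)))
  invisible(x)
}

#' Serialize an ensemble manifest for audit
#'
#' @param model an `ensemble_model`.
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
ensemble_manifest <- function(model, path = NULL) {
  m <- list(task = model$task,
            learners = model$learner_ids,
            weights = model$weights,
            cv_risks = model$cv_risks,
            stack_risk = model$stack_risk,
            folds = max(model$fold),
            seed = model$seed)
  if (!is.null(path))
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(m)
}
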