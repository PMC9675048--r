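#' Fit a generalized low-rank model to an incomplete design matrix
#'
#' Factorizes the column-standardized matrix as `U %*% V` (rank `k`) over the
#' observed cells only, by alternating ridge-regularized least squares:
#' minimize `sum_observed (x - u.v)^2 + reg_weight * (||U||^2 + ||V||^2)`.
#' Quadratic loss is used for all column kinds. Rows sharing a missingness
#' pattern are solved jointly, so the common case of block missingness is
#' fast. The objective is non-increasing across iterations (asserted) and the
#' fit is deterministic given `seed`.
#'
#' @param X a `covmat` or a numeric matrix with `NA`s.
#' @param rank target rank `k` (1 <= k <= min(n, d)).
#' @param reg_weight ridge penalty (>= 0).
#' @param seed integer seed for factor initialization.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum number of alternating sweeps.
#' @return A `glrm_fit`: row factors `U` (n x k), column factors `V` (k x d),
#'   per-column `offset`/`scale`, `objective` trace, `converged` flag.
#' @export
fit_glrm <- function(X, rank = 5L, reg_weight = 0.1, seed = 1L,
                     tol = 1e-6, max_iter = 500L) {
  x <- if (inherits(X, "covmat")) X$x else as.matrix(X)
  n <- nrow(x); d <- ncol(x)
  if (rank < 1 || rank > min(n, d))
    stop_field("rank", sprintf("must be in [1, %d]", min(n, d)))
  check_nonneg(reg_weight, "reg_weight")
  obs <- !is.na(x)
  nobs_col <- colSums(obs)
  if (any(nobs_col == 0))
    stop(sprintf("column(s) with zero observed cells: %s",
                 paste(colnames(x)[nobs_col == 0], collapse = ", ")),
         call. = FALSE)

  offset <- colSums(x * obs, na.rm = TRUE) / nobs_col
  ctr <- sweep(x, 2, offset)
  scale <- sqrt(colSums(ctr^2 * obs, na.rm = TRUE) / pmax(nobs_col - 1, 1))
  scale[scale < 1e-12] <- 1
  z <- sweep(ctr, 2, scale, "/")
  z[!obs] <- 0  # contributes nothing; masked by obs below

  set.seed(substream_seed(seed, "glrm-init"))
  V <- matrix(rnorm(rank * d, sd = 0.1), rank, d)
  U <- matrix(0, n, rank)
  lambda <- reg_weight
  eye <- diag(lambda, rank)

  objective <- function() {
    r <- (z - U %*% V) * obs
    sum(r^2) + lambda * (sum(U^2) + sum(V^2))
  }

  # solve all rows sharing one missingness pattern with a single k x k system
  pat <- apply(obs, 1, function(m) paste(which(!m), collapse = ","))
  pat_groups <- split(seq_len(n), pat)

  obj <- Inf; trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (rows in pat_groups) {
      m <- obs[rows[1], ]
      Vm <- V[, m, drop = FALSE]
      A <- Vm %*% t(Vm) + eye
      B <- Vm %*% t(z[rows, m, drop = FALSE])
      U[rows, ] <- t(solve(A, B))
    }
    for (j in seq_len(d)) {
      rows <- obs[, j]
      Uj <- U[rows, , drop = FALSE]
      V[, j] <- solve(crossprod(Uj) + eye, crossprod(Uj, z[rows, j]))
    }
    new_obj <- objective()
    if (new_obj > obj + 1e-8 * max(1, obj))
      stop("internal error: GLRM objective increased")  # nocov
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(obj - new_obj) <= tol * max(obj, 1e-12)) {
      converged <- TRUE; obj <- new_obj; break
    }
    obj <- new_obj
  }
  structure(list(U = U, V = V, offset = offset, scale = scale,
                 rank = rank, reg_weight = reg_weight,
                 objective = trace, converged = converged,
                 columns = colnames(x)),
            class = "glrm_fit")
}

#' Impute masked cells from a GLRM fit
#'
#' Fills masked cells with the de-standardized low-rank reconstruction
#' `offset + scale * (U %*% V)`; observed cells are left untouched. Indicator
#' columns are clipped to `[0, 1]`.
#'
#' @param X the `covmat` (or matrix) the fit was trained on.
#' @param fit a [fit_glrm()] result.
#' @return A completed object of the same type as `X` (mask retained in the
#'   `covmat` case, recording which cells were imputed).
#' @export
impute_glrm <- function(X, fit) {
  is_cm <- inherits(X, "covmat")
  x <- if (is_cm) X$x else as.matrix(X)
  if (ncol(x) != ncol(fit$V) || nrow(x) != nrow(fit$U))
    stop("dimension mismatch between matrix and GLRM fit", call. = FALSE)
  recon <- sweep(sweep(fit$U %*% fit$V, 2, fit$scale, "*"), 2, fit$offset, "+")
  miss <- is.na(x)
  x[miss] <- recon[miss]
  if (is_cm) {
    ind <- which(X$kind == "indicator")
    x[, ind] <- clip(x[, ind, drop = FALSE], 0, 1)
    X$x <- x
    X
  } else x
}

#' Append non-collinear missingness indicators
#'
#' Adds one 0/1 indicator column per originally-missing predictor column.
#' Indicators with exactly identical missingness patterns are perfectly
#' collinear; only the first (in column order) of each pattern is kept, and
#' constant indicators are dropped.
#'
#' @param X a `covmat` carrying the original missing mask.
#' @return The `covmat` with indicator columns (`kind = "miss_indicator"`,
#'   named `miss:<column>`) appended, plus an `indicator_report` attribute
#'   listing kept and dropped indicators.
#' @export
add_missingness_indicators <- function(X) {
  stopifnot(inherits(X, "covmat"))
  mask <- X$mask
  has_miss <- which(colSums(mask) > 0)
  kept <- integer(0); dropped <- character(0); seen <- character(0)
  for (j in has_miss) {
    m <- mask[, j]
    if (all(m) || !any(m)) { dropped <- c(dropped, colnames(X$x)[j]); next }
    key <- paste(which(m), collapse = ",")
    if (key %in% seen) { dropped <- c(dropped, colnames(X$x)[j]); next }
    seen <- c(seen, key)
    kept <- c(kept, j)
  }
  if (length(kept)) {
    ind <- matrix(as.numeric(mask[, kept, drop = FALSE]), nrow = nrow(mask))
    colnames(ind) <- paste0("miss:", colnames(X$x)[kept])
    X$x <- cbind(X$x, ind)
    X$mask <- cbind(X$mask, matrix(FALSE, nrow(ind), ncol(ind)))
    X$kind <- c(X$kind, rep("miss_indicator", ncol(ind)))
    X$parent <- c(X$parent, paste0("miss:", X$parent[kept]))
  }
  attr(X, "indicator_report") <-
    list(kept = if (length(kept)) paste0("miss:", colnames(X$x)[kept]) else character(0),
         dropped_collinear_or_constant = dropped)
  X
}
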