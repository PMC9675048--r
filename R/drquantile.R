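#' Threshold grid for distribution-function estimation
#'
#' Consumption is pill-discrete, so the grid of thresholds is the set of
#' unique observed values when there are at most `max_points` of them
#' (making the estimated distribution function exact on its support);
#' otherwise 201 equally-spaced quantile knots of the observed values are
#' used. Zero is always included.
#'
#' @param y observed (measured) consumption values.
#' @param max_points grid-size cap.
#' @return Sorted numeric grid.
#' @export
cdf_grid <- function(y, max_points = 201L) {
  u <- sort(unique(c(0, y)))
  if (length(u) <= max_points) return(u)
  sort(unique(c(0, quantile_type1(y, seq(0, 1, length.out = max_points)))))
}

#' Estimate the measurement propensity
#'
#' Fits the ensemble for `P(measured | W)` and truncates the predicted
#' probabilities to `bounds`, so inverse-probability weights `1/g` are
#' bounded above by `1/g_min`.
#'
#' @param X complete design matrix.
#' @param measured_flags 0/1 vector.
#' @param library binary-task learner library.
#' @param bounds truncation interval `(g_min, g_max]` with `g_min > 0`.
#' @param folds,seed passed to [cv_stack()].
#' @return A `propensity_fit`: the ensemble, truncated probabilities `g`,
#'   bounds, and the weight distribution summary.
#' @export
fit_propensity <- function(X, measured_flags, library = NULL,
                           bounds = c(0.01, 1), folds = 10L, seed = 1L) {
  if (bounds[1] <= 0 || bounds[2] > 1 || bounds[1] >= bounds[2])
    stop_field("bounds", "must satisfy 0 < g_min < g_max <= 1")
  if (is.null(library)) library <- default_library("binary")
  model <- cv_stack(X, measured_flags, library, folds = folds,
                    task = "binary", seed = substream_seed(seed, "propensity"))
  g <- clip(predict_ensemble(model, X), bounds[1], bounds[2])
  structure(list(model = model, g = g, bounds = bounds,
                 weight_summary = summary(1 / g)),
            class = "propensity_fit")
}

#' Initial conditional distribution-function regressions
#'
#' For each grid threshold `y_j`, regresses the indicator `1(Y <= y_j)` on
#' the covariates among measured records with the given (continuous-task)
#' library, and records the predicted conditional probability for every
#' record. The initial marginal estimate is the all-records mean of those
#' predictions. Degenerate thresholds (indicator constant among measured)
#' shortcut to the constant.
#'
#' @param X complete design matrix (all records).
#' @param y outcome vector (`NA` where not measured).
#' @param measured_flags 0/1 vector.
#' @param grid thresholds from [cdf_grid()]; all must be `>= 0`.
#' @param library learner library for the indicator regressions.
#' @param folds,seed passed to [cv_stack()].
#' @return A `threshold_fits` object: matrix `Q` (n x m) of conditional
#'   probabilities clipped to `[0, 1]`, the grid, and initial marginal
#'   `F_init`.
#' @export
fit_threshold_regressions <- function(X, y, measured_flags, grid,
                                      library = NULL, folds = 10L, seed = 1L) {
  if (any(grid < 0)) stop_field("grid", "thresholds must be >= 0")
  if (is.null(library)) library <- default_library("continuous")
  m <- length(grid)
  n <- nrow(X)
  idx <- which(measured_flags == 1)
  ym <- y[idx]
  if (any(is.na(ym))) stop("measured records must carry an outcome", call. = FALSE)
  Q <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    z <- as.numeric(ym <= grid[j])
    if (all(z == 1)) { Q[, j] <- 1; next }
    if (all(z == 0)) { Q[, j] <- 0; next }
    fit <- cv_stack(X[idx, , drop = FALSE], z, library, folds = folds,
                    task = "continuous",
                    seed = substream_seed(seed, paste0("cdf", j)))
    Q[, j] <- clip(predict_ensemble(fit, X), 0, 1)
  }
  structure(list(Q = Q, grid = grid, F_init = colMeans(Q),
                 measured = measured_flags, y = y),
            class = "threshold_fits")
}

# one-dimensional logistic fluctuation: maximize the Bernoulli likelihood of
# z against offset + eps * h by Newton; returns NA on failure
solve_epsilon <- function(z, off, h) {
  eps <- 0
  for (it in 1:100) {
    p <- plogis(off + eps * h)
    score <- sum(h * (z - p))
    info <- sum(h^2 * p * (1 - p))
    if (!is.finite(score) || !is.finite(info) || info < 1e-12) return(NA_real_)
    delta <- score / info
    eps <- eps + delta
    if (abs(eps) > 50) return(NA_real_)
    if (abs(score) / length(z) < 1e-12 || abs(delta) < 1e-11) return(eps)
  }
  NA_real_
}

#' Targeting step: fluctuate the conditional CDF fits
#'
#' For each threshold, performs a one-dimensional logistic fluctuation of the
#' conditional predictions with clever covariate `H(W) = measured / g(W)`:
#' `eps_j` maximizes the Bernoulli likelihood of `1(Y <= y_j)` among measured
#' records against offset `logit(prediction) + eps * (1/g)`; the targeted
#' marginal is the all-records mean of the fluctuated predictions. If the
#' Newton solve fails, a closed-form weighted-intercept update (weights
#' `1/g`) is used instead and logged. The targeted curve is then monotonized
#' by isotonic regression (values already monotone are preserved). The
#' per-threshold influence curve
#' `IC = (M/g) (Z - Q*) + Q* - F_hat` has mean zero by construction; its
#' sample variance yields pointwise Wald standard errors.
#'
#' @param fits a [fit_threshold_regressions()] result.
#' @param propensity a [fit_propensity()] result on the same records.
#' @return A `targeted_cdf`: grid, initial and targeted values, epsilon per
#'   threshold, standard errors, influence-curve matrix, `n`.
#' @export
target_cdf <- function(fits, propensity) {
  g <- propensity$g
  M <- fits$measured
  n <- length(M)
  if (length(g) != n) stop("propensity and fits cover different records",
                           call. = FALSE)
  grid <- fits$grid
  m <- length(grid)
  idx <- which(M == 1)
  ym <- fits$y[idx]
  h_all <- 1 / g
  F_hat <- numeric(m); eps_vec <- numeric(m); se <- numeric(m)
  IC <- matrix(0, n, m)
  fallback <- 0L
  for (j in seq_len(m)) {
    z <- as.numeric(ym <= grid[j])
    Q <- clip(fits$Q[, j], 1e-6, 1 - 1e-6)
    if (all(z == 1) || all(z == 0)) {
      Fj <- mean(z)  # 0 or 1; influence curve identically zero
      F_hat[j] <- Fj; eps_vec[j] <- 0; se[j] <- 0
      next
    }
    off <- logit(Q[idx])
    eps <- solve_epsilon(z, off, h_all[idx])
    if (is.na(eps)) {
      # weighted-intercept fallback: solve sum (1/g) (z - plogis(off + e)) = 0
      fallback <- fallback + 1L
      w <- h_all[idx]
      f <- function(e) sum(w * (z - plogis(off + e)))
      eps <- tryCatch(stats::uniroot(f, c(-30, 30))$root, error = function(e) 0)
      Qstar <- plogis(logit(Q) + eps)
    } else {
      Qstar <- plogis(logit(Q) + eps * h_all)
    }
    Fj <- mean(Qstar)
    zfull <- numeric(n); zfull[idx] <- z
    ic <- (M / g) * (zfull - Qstar) + Qstar - Fj
    F_hat[j] <- Fj
    eps_vec[j] <- eps
    se[j] <- sqrt(var(ic) / n)
    IC[, j] <- ic
  }
  if (fallback > 0)
    message(sprintf("targeting fell back to weighted-intercept update at %d threshold(s)",
                    fallback))
  F_mono <- clip(isoreg(seq_len(m), F_hat)$yf, 0, 1)
  structure(list(grid = grid, F_init = fits$F_init, F_raw = F_hat,
                 F = F_mono, epsilon = eps_vec, se = se, IC = IC,
                 n = n, n_measured = length(idx)),
            class = "targeted_cdf")
}

#' Invert a targeted distribution function into a quantile estimate
#'
#' Point estimate: smallest grid threshold with `F_hat >= level`
#' (left-continuous generalized inverse). The 95% confidence interval inverts
#' the pointwise Wald band on the distribution function: the lower limit is
#' the smallest threshold with `F_hat + 1.96 se >= level`, the upper limit
#' the smallest with `F_hat - 1.96 se >= level` (band inversion avoids
#' density estimation).
#'
#' @param tcdf a [target_cdf()] result.
#' @param level quantile level in (0, 1).
#' @param procedure_group label carried into the output.
#' @return One-row data.frame (`quantile_estimate`): level, point, ci_low,
#'   ci_high, n_total, n_measured, method = `"adjusted"`.
#' @export
invert_quantile <- function(tcdf, level, procedure_group = NA_character_) {
  if (level <= 0 || level >= 1) stop_field("level", "must be in (0, 1)")
  Fh <- tcdf$F; se <- tcdf$se; grid <- tcdf$grid
  if (max(Fh) < level)
    stop(sprintf("grid too short: max F = %.4f < level %.2f", max(Fh), level),
         call. = FALSE)
  pick <- function(vals) {
    i <- which(vals >= level - 1e-9)  # floating-point guard at exact ties
    if (!length(i)) grid[length(grid)] else grid[min(i)]
  }
  data.frame(procedure_group = procedure_group, level = level,
             method = "adjusted",
             point = pick(Fh),
             ci_low = pick(Fh + 1.96 * se),
             ci_high = pick(Fh - 1.96 * se),
             n_total = tcdf$n, n_measured = tcdf$n_measured,
             stringsAsFactors = FALSE)
}

#' Unadjusted (responder-only) empirical quantile
#'
#' Type-1 (inverted ECDF) sample quantile of the measured values, with an
#' order-statistic (binomial) 95% confidence interval.
#'
#' @param measured_y measured consumption values.
#' @param level quantile level in (0, 1).
#' @param procedure_group label carried into the output.
#' @return One-row `quantile_estimate` data.frame, method = `"unadjusted"`.
#' @export
unadjusted_quantile <- function(measured_y, level,
                                procedure_group = NA_character_) {
  measured_y <- measured_y[!is.na(measured_y)]
  if (!length(measured_y)) stop("no measured values", call. = FALSE)
  if (level <= 0 || level >= 1) stop_field("level", "must be in (0, 1)")
  ys <- sort(measured_y)
  n <- length(ys)
  lo <- max(1L, qbinom(0.025, n, level))
  hi <- min(n, qbinom(0.975, n, level) + 1L)
  data.frame(procedure_group = procedure_group, level = level,
             method = "unadjusted",
             point = quantile_type1(ys, level),
             ci_low = ys[lo], ci_high = ys[hi],
             n_total = n, n_measured = n,
             stringsAsFactors = FALSE)
}

#' Full nonresponse-adjusted quantile estimation for one cohort
#'
#' Runs the complete targeted-learning pipeline on one patient table:
#' known-zero assignment, design matrix, low-rank imputation with
#' missingness indicators (when covariates are missing), measurement
#' propensity, per-threshold conditional CDF regressions, targeting,
#' monotonization and inversion. The default estimand population is
#' `"prescribed"` (consumption among patients with a nonzero opioid
#' prescription, the population the outcome regression is fit on); the
#' `"all"` population mixes a point mass at zero with weight equal to the
#' unprescribed fraction into the targeted distribution.
#'
#' @param records patient table.
#' @param levels quantile levels.
#' @param population `"prescribed"` or `"all"`.
#' @param propensity_library,cdf_library learner libraries (defaults: task
#'   defaults; see [default_library()]).
#' @param bounds propensity truncation bounds.
#' @param folds cross-validation folds for both nuisance fits.
#' @param grid_max grid-size cap for [cdf_grid()].
#' @param predictor_spec see [build_design_matrix()].
#' @param glrm_rank imputation rank (used only if covariates are missing).
#' @param seed integer seed.
#' @param procedure_group label carried into outputs.
#' @return list with `estimates` (adjusted and unadjusted rows per level),
#'   `tcdf`, `propensity`.
#' @export
adjust_quantiles <- function(records, levels = c(0.5, 0.75),
                             population = c("prescribed", "all"),
                             propensity_library = NULL, cdf_library = NULL,
                             bounds = c(0.01, 1), folds = 10L,
                             grid_max = 201L,
                             predictor_spec = default_predictor_spec(),
                             glrm_rank = 5L, seed = 1L,
                             procedure_group = NA_character_) {
  population <- match.arg(population)
  records <- assign_known_zeros(records)
  zero_frac <- mean(records$prescribed_mme == 0)
  presc <- records[records$prescribed_mme > 0, , drop = FALSE]
  if (!nrow(presc)) stop("no prescribed patients", call. = FALSE)
  if (sum(presc$measured) == 0) stop("no measured records", call. = FALSE)

  cm <- build_design_matrix(presc, predictor_spec)
  if (any(cm$mask)) {
    fit <- fit_glrm(cm, rank = min(glrm_rank, ncol(cm$x) - 1L),
                    seed = substream_seed(seed, "glrm"))
    cm <- impute_glrm(cm, fit)
    cm <- add_missingness_indicators(cm)
  }
  X <- cm$x

  prop <- fit_propensity(X, presc$measured, library = propensity_library,
                         bounds = bounds, folds = folds, seed = seed)
  ym <- presc$consumed_mme
  grid <- cdf_grid(ym[presc$measured == 1], grid_max)
  fits <- fit_threshold_regressions(X, ym, presc$measured, grid,
                                    library = cdf_library, folds = folds,
                                    seed = seed)
  tc <- target_cdf(fits, prop)

  if (population == "all") {
    # exact zeros from unprescribed patients enter as a point mass
    tc$F <- clip(zero_frac + (1 - zero_frac) * tc$F, 0, 1)
    tc$se <- (1 - zero_frac) * tc$se
    tc$n <- nrow(records)
    tc$n_measured <- sum(records$measured)
  }
  measured_y <- if (population == "all") {
    records$consumed_mme[records$measured == 1]
  } else ym[presc$measured == 1]

  est <- do.call(rbind, c(
    lapply(levels, function(l) invert_quantile(tc, l, procedure_group)),
    lapply(levels, function(l) unadjusted_quantile(measured_y, l,
                                                   procedure_group))))
  list(estimates = est, tcdf = tc, propensity = prop)
}

#' Per-procedure adjusted and unadjusted quantile estimates
#'
#' Runs [adjust_quantiles()] within each procedure group. Groups below the
#' minimum size, or with no measured records, are skipped with a notice.
#'
#' @param records patient table with `procedure_group`.
#' @param levels quantile levels.
#' @param min_n minimum group size.
#' @param ... passed to [adjust_quantiles()].
#' @return data.frame of quantile estimates (all groups stacked), with a
#'   `skipped` attribute naming skipped groups.
#' @export
estimate_by_procedure <- function(records, levels = c(0.5, 0.75),
                                  min_n = 30L, ...) {
  groups <- sort(unique(records$procedure_group))
  skipped <- character(0)
  out <- list()
  for (gp in groups) {
    r <- records[records$procedure_group == gp, , drop = FALSE]
    if (nrow(r) < min_n) {
      message(sprintf("skipping '%s': n = %d < %d", gp, nrow(r), min_n))
      skipped <- c(skipped, gp); next
    }
    res <- tryCatch(
      adjust_quantiles(r, levels = levels, procedure_group = gp, ...),
      error = function(e) {
        message(sprintf("skipping '%s': %s", gp, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) { skipped <- c(skipped, gp); next }
    out[[gp]] <- res$estimates
  }
  est <- do.call(rbind, out)
  rownames(est) <- NULL
  attr(est, "skipped") <- skipped
  est
}
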