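#' Random-forest pre-screening of whole variables
#'
#' Ranks variables by random-forest impurity importance (total SSE reduction
#' across all splits) and retains the top `k`. Categorical variables are
#' screened whole — they enter the forest as single integer-coded columns,
#' before any indicator encoding. Deterministic given `seed`.
#'
#' @param X data.frame or numeric matrix of predictors (factors/characters
#'   are integer-coded internally).
#' @param y outcome (numeric or 0/1).
#' @param k number of variables to keep.
#' @param ntree,seed forest settings.
#' @return Character vector of the `k` retained variable names, importance
#'   order.
#' @export
rf_screen <- function(X, y, k = 25L, ntree = 200L, seed = 1L) {
  if (k <= 0) stop_field("k", "must be positive")
  Xm <- encode_whole(X)
  k <- min(k, ncol(Xm))
  fit <- .rf_fit_cpp(Xm, as.numeric(y), as.integer(ntree),
                     max(1L, floor(ncol(Xm) / 3)), 5L, 25L, 1.0, TRUE,
                     as.integer(substream_seed(seed, "rf_screen")))
  imp <- setNames(fit$importance, colnames(Xm))
  names(sort(imp, decreasing = TRUE))[seq_len(k)]
}

# integer-code factor/character columns, keep numerics; missing categories
# become their own code (0), missing numerics take the column median
encode_whole <- function(X) {
  df <- as.data.frame(X, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      code <- as.integer(factor(v))
      code[is.na(code)] <- 0L
      df[[nm]] <- code
    } else {
      v <- as.numeric(v)
      v[is.na(v)] <- median(v, na.rm = TRUE)
      df[[nm]] <- v
    }
  }
  as.matrix(df)
}

#' Split-count variable importance from a tree ensemble
#'
#' Computes each variable's share of all decision-tree splits across the
#' ensemble. Indicator columns belonging to one categorical variable are
#' aggregated back to the parent variable (by the supplied mapping) before
#' ranking. Shares are non-negative and sum to 1.
#'
#' @param forest a fitted forest (`$forest` element of an [lrn_rf()] fit, or
#'   the raw list from the internal engine) exposing `split_counts`.
#' @param variables column names parallel to the forest's design matrix.
#' @param parent optional mapping (same length) from column to parent
#'   variable; defaults to the columns themselves.
#' @return An `importance_table` data.frame: variable, share, rank.
#' @export
split_count_importance <- function(forest, variables, parent = variables) {
  counts <- forest$split_counts
  if (sum(counts) == 0) stop("ensemble contains zero splits", call. = FALSE)
  agg <- tapply(counts, parent, sum)
  share <- as.numeric(agg) / sum(counts)
  ord <- order(share, decreasing = TRUE)
  data.frame(variable = names(agg)[ord], share = share[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Variable-importance analysis for measurement and consumption
#'
#' Produces the two importance rankings of the analysis, both restricted to
#' patients prescribed opioids: (a) which variables drive the ability to
#' measure consumption (the response/measurement flag), and (b) which drive
#' consumed MMEs among measured patients. Each target is pre-screened to the
#' top `k` variables by random-forest impurity importance (categoricals kept
#' whole), then split counts of a dedicated tallying forest are aggregated to
#' parent variables. Variables appearing in the top ranks of both tables are
#' flagged as observed confounders — overlap between predictors of response
#' and predictors of consumption is the signature of nonresponse bias.
#'
#' In this build the tallying ensemble is the package's random forest (no
#' sum-of-trees sampler is available in the environment); the result records
#' which engine was used.
#'
#' @param records patient table.
#' @param variables predictor columns to analyse.
#' @param k screening size.
#' @param ntree tallying-forest size.
#' @param overlap_top overlap window for the confounder flag.
#' @param seed integer seed.
#' @return list with `measurement` and `consumption` importance tables,
#'   `confounders` (overlap of the two top-`overlap_top` sets), and
#'   `engine`.
#' @export
importance_analysis <- function(records,
                                variables = c("age_years", "sex", "race",
                                              "tobacco_use", "alcohol_use",
                                              "asa_class", "los_category",
                                              "preop_assessment",
                                              "prescribed_mme",
                                              "discharge_day_mme",
                                              "opioid_drugs_prescribed"),
                                k = 25L, ntree = 500L, overlap_top = 5L,
                                seed = 1L) {
  presc <- records[records$prescribed_mme > 0, , drop = FALSE]
  meas <- presc[presc$measured == 1, , drop = FALSE]
  if (nrow(meas) < 50)
    stop("fewer than 50 prescribed-measured records", call. = FALSE)

  one_table <- function(data, y, stage) {
    keep <- rf_screen(data[, variables, drop = FALSE], y, k = k,
                      seed = substream_seed(seed, paste0(stage, "_screen")))
    Xm <- encode_whole(data[, keep, drop = FALSE])
    # tallying ensemble: many shallow trees (the sum-of-trees regime), so
    # split counts concentrate on genuine signal instead of deep noise splits
    fit <- .rf_fit_cpp(Xm, as.numeric(y), as.integer(ntree),
                       max(1L, floor(ncol(Xm) / 3)), 50L, 2L, 1.0, TRUE,
                       as.integer(substream_seed(seed, paste0(stage, "_tally"))))
    tab <- split_count_importance(fit, colnames(Xm))
    attr(tab, "screened") <- keep
    tab
  }
  meas_tab <- one_table(presc, presc$measured, "measurement")
  cons_tab <- one_table(meas, meas$consumed_mme, "consumption")
  confounders <- intersect(head(meas_tab$variable, overlap_top),
                           head(cons_tab$variable, overlap_top))
  list(measurement = meas_tab, consumption = cons_tab,
       confounders = confounders, engine = "random_forest",
       seed = seed)
}
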