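#' Bin a continuous covariate
#'
#' Groups a continuous variable into discrete bins either at stated clinical
#' thresholds or at sample quantiles. Bins are closed on the left, open on
#' the right, with the last bin closed. Values below the first clinical
#' threshold fall in a declared `"<lo>"` underflow bin with a warning.
#'
#' @param values numeric vector (may contain `NA`, which stays `NA`).
#' @param scheme `list(type = "thresholds", edges = <increasing numeric>)` or
#'   `list(type = "quantiles", k = <integer >= 2>)`.
#' @return A factor of bin labels.
#' @export
bin_continuous <- function(values, scheme) {
  if (scheme$type == "thresholds") {
    edges <- scheme$edges
    if (is.unsorted(edges, strictly = TRUE))
      stop_field("edges", "must be strictly increasing")
    labs <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
    labs[length(labs)] <- sub("\\)$", "]", labs[length(labs)])
    under <- !is.na(values) & values < edges[1]
    if (any(under)) {
      warning(sprintf("%d value(s) below first threshold assigned to underflow bin",
                      sum(under)))
      out <- cut(values, breaks = c(-Inf, edges), right = FALSE,
                 include.lowest = TRUE,
                 labels = c(sprintf("<%s", edges[1]), labs))
    } else {
      out <- cut(values, breaks = edges, right = FALSE, include.lowest = TRUE,
                 labels = labs)
    }
    out
  } else if (scheme$type == "quantiles") {
    k <- scheme$k
    if (is.null(k) || k < 2) stop_field("k", "must be >= 2")
    qs <- quantile(values, probs = seq(0, 1, length.out = k + 1), na.rm = TRUE)
    qs[1] <- -Inf; qs[k + 1] <- Inf
    cut(values, breaks = unique(qs), right = FALSE, include.lowest = TRUE)
  } else stop_field("scheme$type", "must be 'thresholds' or 'quantiles'")
}

#' Chi-squared association between a binned covariate and response/measurement
#'
#' Pearson chi-squared test on the levels-by-outcome contingency table, with
#' Yates continuity correction if and only if the table is 2x2 (the
#' convention that reproduces the printed sex-row p-value of the source
#' cohort diagnostics). Records with a missing covariate value are excluded
#' from that covariate's test (complete case per covariate); when
#' `exclude_zero_rx`, zero-prescription patients are removed first — they
#' have a 100% measurement rate by construction and would distort the
#' measurement test.
#'
#' @param records patient table.
#' @param covariate name of a categorical (post-binning) column.
#' @param outcome_flag `"responded"` or `"measured"`.
#' @param exclude_zero_rx drop `prescribed_mme == 0` records first.
#' @return A `bivariate_result`: data.frame of per-level `n` and rate (%),
#'   with attributes `statistic`, `df`, `p_value`, `outcome`,
#'   `zero_rx_excluded`.
#' @export
test_association <- function(records, covariate, outcome_flag = c("responded", "measured"),
                             exclude_zero_rx = FALSE) {
  outcome_flag <- match.arg(outcome_flag)
  if (!covariate %in% names(records))
    stop(sprintf("covariate '%s' not found", covariate), call. = FALSE)
  if (exclude_zero_rx) records <- records[records$prescribed_mme > 0, , drop = FALSE]
  keep <- !is.na(records[[covariate]])
  records <- records[keep, , drop = FALSE]
  lv <- records[[covariate]]
  if (is.factor(lv)) lv <- droplevels(lv)
  y <- records[[outcome_flag]]
  tab <- table(lv, factor(y, levels = c(0, 1)))
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_counts == 0))
    stop("contingency table has an expected cell count of zero", call. = FALSE)
  if (any(exp_counts < 5))
    warning("expected cell count < 5; chi-squared approximation may be poor")
  yates <- all(dim(tab) == c(2L, 2L))
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  res <- data.frame(covariate = covariate,
                    level = rownames(tab),
                    n = as.integer(rowSums(tab)),
                    rate_pct = 100 * tab[, "1"] / rowSums(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "statistic") <- unname(ct$statistic)
  attr(res, "df") <- unname(ct$parameter)
  attr(res, "p_value") <- unname(ct$p.value)
  attr(res, "outcome") <- outcome_flag
  attr(res, "zero_rx_excluded") <- exclude_zero_rx
  attr(res, "yates") <- yates
  class(res) <- c("bivariate_result", "data.frame")
  res
}

#' Two-sample Kolmogorov-Smirnov comparison of raw continuous covariates
#'
#' @param values_group1,values_group2 numeric vectors (`NA` dropped).
#' @return `list(statistic, p_value)`; the statistic is
#'   `sup |ECDF1 - ECDF2|` with the asymptotic p-value.
#' @export
ks_compare <- function(values_group1, values_group2) {
  v1 <- values_group1[!is.na(values_group1)]
  v2 <- values_group2[!is.na(values_group2)]
  if (!length(v1) || !length(v2))
    stop("both groups must contain non-missing values", call. = FALSE)
  kt <- suppressWarnings(ks.test(v1, v2, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Monthly response, prescription and measurement rates
#'
#' @param records patient table with `discharge_month`.
#' @return data.frame of per-month `n`, `response_rate`, `any_rx_rate`,
#'   `measured_rate`; months with zero patients are omitted.
#' @export
temporal_rates <- function(records) {
  months <- sort(unique(records$discharge_month))
  out <- lapply(months, function(m) {
    r <- records[records$discharge_month == m, ]
    data.frame(month = m, n = nrow(r),
               response_rate = mean(r$responded),
               any_rx_rate = mean(r$prescribed_mme > 0),
               measured_rate = mean(r$measured),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full bivariate diagnostic table
#'
#' Runs [test_association()] for each listed covariate against both survey
#' response and consumption measurement, mirroring the layout of the source
#' study's bivariate table (covariate, level, N, rate, p). The measurement
#' test for prescription-size bins excludes zero-prescription patients.
#'
#' @param records patient table; continuous covariates should be binned
#'   first (see [bin_continuous()] / `derive_bins`).
#' @param covariates character vector of categorical columns.
#' @param exclude_zero_rx named logical vector (per covariate) for the
#'   measurement-side exclusion; default `FALSE` except `rx_bin`.
#' @return data.frame with columns covariate, level, n, response_pct,
#'   response_p, measured_pct, measured_p (p-values formatted to 3 decimals,
#'   `<0.001` below that).
#' @export
bivariate_table <- function(records,
                            covariates = c("age_bin", "sex", "race",
                                           "los_category", "tobacco_use",
                                           "alcohol_use", "asa_class",
                                           "rx_bin", "ddmme_bin"),
                            exclude_zero_rx = c(rx_bin = TRUE)) {
  records <- derive_bins(records)
  rows <- lapply(covariates, function(cv) {
    ex <- isTRUE(exclude_zero_rx[cv])
    resp <- test_association(records, cv, "responded", exclude_zero_rx = FALSE)
    # rates are displayed on all records; the test may exclude zero-rx rows
    meas_disp <- test_association(records, cv, "measured", exclude_zero_rx = FALSE)
    meas_p <- attr(test_association(records, cv, "measured",
                                    exclude_zero_rx = ex), "p_value")
    data.frame(covariate = cv, level = resp$level, n = resp$n,
               response_pct = round(resp$rate_pct, 1),
               response_p = format_pval(attr(resp, "p_value")),
               measured_pct = round(meas_disp$rate_pct, 1),
               measured_p = format_pval(meas_p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
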