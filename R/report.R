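#' Summary of nonresponse-adjustment corrections
#'
#' For each procedure group and level, the correction is the absolute
#' relative change `100 * |adjusted - unadjusted| / unadjusted` (percent).
#' Groups with an unadjusted estimate of zero have an undefined correction:
#' they are reported as `NA` and excluded from the mean and interquartile
#' range. A signed variant is available via `signed = TRUE`.
#'
#' @param estimates data.frame of quantile estimates (adjusted and
#'   unadjusted rows, as from [estimate_by_procedure()]).
#' @param levels quantile levels to summarize.
#' @param signed report signed relative change instead of absolute.
#' @return list per level: per-group corrections, `mean`, `iqr`
#'   (25th/75th percentiles across groups).
#' @export
correction_summary <- function(estimates, levels = c(0.5, 0.75),
                               signed = FALSE) {
  out <- list()
  for (lv in levels) {
    adj <- estimates[estimates$level == lv & estimates$method == "adjusted", ]
    una <- estimates[estimates$level == lv & estimates$method == "unadjusted", ]
    extra <- union(setdiff(adj$procedure_group, una$procedure_group),
                   setdiff(una$procedure_group, adj$procedure_group))
    if (length(extra))
      stop(sprintf("group(s) present on one side only: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    una <- una[match(adj$procedure_group, una$procedure_group), ]
    rel <- 100 * (adj$point - una$point) / una$point
    if (!signed) rel <- abs(rel)
    rel[una$point == 0] <- NA
    ok <- !is.na(rel)
    out[[as.character(lv)]] <- list(
      corrections = setNames(rel, adj$procedure_group),
      mean = mean(rel[ok]),
      iqr = unname(quantile(rel[ok], c(0.25, 0.75))),
      undefined = adj$procedure_group[!ok])
  }
  out
}

#' Compare adjusted and unadjusted estimates against a reference survey
#'
#' Per group and level, the adjusted estimate is "closer" when
#' `|adjusted - reference| < |unadjusted - reference|`; ties count as
#' "unchanged". Groups missing from the reference are excluded with a
#' notice.
#'
#' @param estimates estimates table (adjusted + unadjusted rows).
#' @param reference data.frame with `procedure_group`, `level`, `point`
#'   (the external reference quantiles).
#' @param levels levels to compare.
#' @return list per level: per-group verdicts and the `closer`/`n` tally.
#' @export
compare_reference <- function(estimates, reference, levels = c(0.5, 0.75)) {
  out <- list()
  for (lv in levels) {
    adj <- estimates[estimates$level == lv & estimates$method == "adjusted", ]
    una <- estimates[estimates$level == lv & estimates$method == "unadjusted", ]
    ref <- reference[reference$level == lv, ]
    miss <- setdiff(adj$procedure_group, ref$procedure_group)
    if (length(miss))
      message(sprintf("excluded from reference comparison (no reference): %s",
                      paste(miss, collapse = ", ")))
    groups <- intersect(adj$procedure_group, ref$procedure_group)
    verdict <- vapply(groups, function(gp) {
      a <- adj$point[adj$procedure_group == gp]
      u <- una$point[una$procedure_group == gp]
      r <- ref$point[ref$procedure_group == gp]
      da <- abs(a - r); du <- abs(u - r)
      if (da < du) "closer" else if (da > du) "farther" else "unchanged"
    }, character(1))
    out[[as.character(lv)]] <- list(
      verdicts = verdict,
      closer = sum(verdict == "closer"),
      n = length(verdict),
      tally = sprintf("%d/%d", sum(verdict == "closer"), length(verdict)))
  }
  out
}

#' Prescription-versus-consumption gap
#'
#' Among prescribed patients with measured consumption, the ratio of the
#' consumption quantile to the prescription quantile at each level, per
#' group and pooled, plus the unconsumed share (`100 - ratio`).
#'
#' @param records patient table.
#' @param levels quantile levels.
#' @param by_group also report per procedure group.
#' @return data.frame: group (`"(pooled)"` row included), level,
#'   consumption_q, prescription_q, ratio_pct, unconsumed_pct.
#' @export
prescription_gap <- function(records, levels = c(0.5, 0.75),
                             by_group = TRUE) {
  r <- records[records$prescribed_mme > 0 & records$measured == 1, ]
  one <- function(d, label) {
    do.call(rbind, lapply(levels, function(lv) {
      qc <- quantile_type1(d$consumed_mme, lv)
      qp <- quantile_type1(d$prescribed_mme, lv)
      if (qp == 0) stop("zero prescription quantile", call. = FALSE)
      data.frame(group = label, level = lv, consumption_q = qc,
                 prescription_q = qp, ratio_pct = 100 * qc / qp,
                 unconsumed_pct = 100 - 100 * qc / qp,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one(r, "(pooled)")
  if (by_group)
    for (gp in sort(unique(r$procedure_group)))
      out <- rbind(out, one(r[r$procedure_group == gp, ], gp))
  rownames(out) <- NULL
  out
}

#' Rolling window quantile trend
#'
#' Per window-end month, the empirical `level`-quantile of measured
#' consumption within the trailing `window_months` window for one procedure
#' group. Windows with fewer than `min_n` measured records are omitted.
#'
#' @param records patient table.
#' @param group procedure group label.
#' @param level quantile level.
#' @param window_months trailing window length (>= 1).
#' @param min_n minimum measured records per window.
#' @param prescribed_only restrict to prescribed patients (default), matching
#'   the estimand population; otherwise known zeros dominate low quantiles.
#' @return data.frame: month, quantile_mme, n.
#' @export
rolling_quantile_trend <- function(records, group, level = 0.75,
                                   window_months = 3L, min_n = 10L,
                                   prescribed_only = TRUE) {
  if (window_months < 1) stop_field("window_months", "must be >= 1")
  if (!group %in% records$procedure_group)
    stop(sprintf("unknown procedure group '%s'", group), call. = FALSE)
  r <- records[records$procedure_group == group & records$measured == 1, ]
  if (prescribed_only) r <- r[r$prescribed_mme > 0, ]
  months <- sort(unique(records$discharge_month))
  out <- list()
  for (i in seq_along(months)) {
    win <- months[max(1, i - window_months + 1):i]
    d <- r[r$discharge_month %in% win, ]
    if (nrow(d) < min_n) next
    out[[months[i]]] <- data.frame(month = months[i],
                                   quantile_mme = quantile_type1(d$consumed_mme, level),
                                   n = nrow(d), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

round_mme <- function(x) round(x, 1)

#' Write the full report bundle
#'
#' Produces the analysis artifacts as delimited text / JSON in an output
#' directory: cohort summary, bivariate diagnostic table, monthly rate
#' series, quantile estimate comparison, correction summary, trend series,
#' and a run manifest (seeds, library, versions). MMEs and rates are
#' rounded to one decimal.
#'
#' @param outputs named list with elements `records`, `estimates`, and
#'   optionally `reference`, `trend_groups` (labels for trend series).
#' @param outdir output directory (created if needed).
#' @param seed root seed recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(outputs, outdir, seed = NA_integer_) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory", call. = FALSE)
  records <- outputs$records
  estimates <- outputs$estimates
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    data.table::fwrite(data.table::as.data.table(df), p)
    paths <<- c(paths, p)
  }

  b <- derive_bins(records)
  cohort_summary <- do.call(rbind, lapply(
    c("age_bin", "race", "los_category", "tobacco_use", "rx_bin"),
    function(cv) {
      t1 <- table(b[[cv]])
      data.frame(characteristic = cv, level = names(t1),
                 n = as.integer(t1),
                 pct = round(100 * as.integer(t1) / sum(!is.na(b[[cv]])), 1),
                 stringsAsFactors = FALSE)
    }))
  wr(cohort_summary, "table1_cohort_summary.csv")
  wr(bivariate_table(records), "table2_bivariate.csv")
  tr <- temporal_rates(records)
  tr[-(1:2)] <- lapply(tr[-(1:2)], function(x) round(100 * x, 1))
  wr(tr, "fig2_temporal_rates.csv")
  est_out <- estimates
  for (cl in c("point", "ci_low", "ci_high")) est_out[[cl]] <- round_mme(est_out[[cl]])
  wr(est_out, "fig4_estimates.csv")
  cs <- correction_summary(estimates)
  p <- file.path(outdir, "correction_summary.json")
  jsonlite::write_json(cs, p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  trend_groups <- outputs$trend_groups %||%
    utils::head(names(sort(table(records$procedure_group), decreasing = TRUE)), 3)
  trends <- do.call(rbind, lapply(trend_groups, function(gp) {
    tr <- rolling_quantile_trend(records, gp)
    if (is.null(tr)) return(NULL)
    tr$group <- gp
    tr
  }))
  if (is.null(trends))
    trends <- data.frame(month = character(0), quantile_mme = numeric(0),
                         n = integer(0), group = character(0))
  wr(trends, "fig5_trend_series.csv")
  manifest <- list(seed = seed,
                   n_records = nrow(records),
                   files = basename(c(paths, file.path(outdir, "manifest.json"))),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("nradjust")))
  p <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
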