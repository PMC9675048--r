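#' Eligibility filtering with per-rule exclusion tallies
#'
#' Applies a list of data-driven eligibility rules to a patient table in
#' declared order and reports how many records each rule excluded. Rules are
#' configuration, not code, so simulated violations can be planted and
#' recounted.
#'
#' @param records patient table.
#' @param rules named list; each rule is `list(field, op, value)` with
#'   `op` one of `">=", "<=", ">", "<", "==", "!=", "%in%"`. A record passes a
#'   rule when the predicate holds.
#' @return `list(records = <passing records>, report = <data.frame rule_id,
#'   excluded>)`; tallies are computed sequentially so they sum to
#'   `nrow(input) - nrow(output)`.
#' @examples
#' rules <- list(adult = list(field = "age_years", op = ">=", value = 18))
#' @export
apply_eligibility <- function(records, rules) {
  report <- data.frame(rule_id = character(0), excluded = integer(0),
                       stringsAsFactors = FALSE)
  for (rid in names(rules)) {
    rule <- rules[[rid]]
    if (!rule$field %in% names(records))
      stop(sprintf("eligibility rule '%s' references absent field '%s'",
                   rid, rule$field), call. = FALSE)
    x <- records[[rule$field]]
    keep <- switch(rule$op,
      ">=" = x >= rule$value, "<=" = x <= rule$value,
      ">"  = x >  rule$value, "<"  = x <  rule$value,
      "==" = x == rule$value, "!=" = x != rule$value,
      "%in%" = x %in% rule$value,
      stop(sprintf("eligibility rule '%s': unknown operator '%s'", rid,
                   rule$op), call. = FALSE))
    keep[is.na(keep)] <- FALSE
    report <- rbind(report, data.frame(rule_id = rid,
                                       excluded = sum(!keep),
                                       stringsAsFactors = FALSE))
    records <- records[keep, , drop = FALSE]
  }
  list(records = records, report = report)
}

#' Morphine milligram equivalent conversion
#'
#' `pills_to_mme` converts a pill count to MMEs given tablet strength and
#' the drug's morphine-equivalence factor. `default_mme_table` provides
#' published equianalgesic factors (per-mg conversion to oral morphine) for
#' common discharge opioids; it is configuration and can be overridden.
#'
#' @param pill_count number of pills (>= 0).
#' @param strength_mg per-pill strength in mg (>= 0).
#' @param factor morphine-equivalence factor (> 0).
#' @return MMEs: `pill_count * strength_mg * factor`.
#' @export
pills_to_mme <- function(pill_count, strength_mg, factor) {
  check_nonneg(pill_count, "pill_count")
  check_nonneg(strength_mg, "strength_mg")
  if (any(factor <= 0)) stop_field("factor", "must be strictly positive")
  pill_count * strength_mg * factor
}

#' @rdname pills_to_mme
#' @export
default_mme_table <- function() {
  data.frame(
    opioid = c("oxycodone", "hydrocodone", "hydromorphone", "morphine",
               "tramadol", "codeine", "oxymorphone", "tapentadol"),
    factor = c(1.5, 1, 4, 1, 0.1, 0.15, 3, 0.4),
    stringsAsFactors = FALSE)
}

#' Designate unprescribed patients as measured zero consumers
#'
#' Patients with no opioid prescription at discharge (per the EHR) have known
#' zero post-discharge opioid consumption: their `measured` flag is set and
#' `consumed_mme` is 0, regardless of survey response. The operation is
#' idempotent and leaves prescribed patients unchanged. A zero-prescription
#' record carrying a nonzero reported consumption is internally inconsistent:
#' it is flagged (`zero_rx_conflict`) with a warning and the reported value is
#' kept.
#'
#' @param records patient table with `prescribed_mme` present for all rows.
#' @return The table with known zeros assigned.
#' @export
assign_known_zeros <- function(records) {
  if (any(is.na(records$prescribed_mme)))
    stop("prescribed_mme must be present for all records", call. = FALSE)
  zero <- records$prescribed_mme == 0
  conflict <- zero & !is.na(records$consumed_mme) & records$consumed_mme > 0
  if (any(conflict)) {
    warning(sprintf(
      "%d zero-prescription record(s) report nonzero consumption; kept and flagged",
      sum(conflict)))
    records$zero_rx_conflict <- conflict
  }
  records$measured[zero] <- 1L
  records$consumed_mme[zero & !conflict] <- 0
  records
}

#' Default predictor specification for the synthetic cohort schema
#'
#' Lists the predictors entering the design matrix, with encoding: numeric
#' passthrough or category-to-indicator with a stated reference level.
#' Bin edges for display/stratification mirror the clinical groupings used
#' throughout (age 18-45/46-60/61-70/71-95; prescribed MMEs 0/1-99/100-299/
#' 300+; discharge-day MMEs 0/1-10/>10).
#'
#' @return A list of predictor entries `list(name, kind, levels, reference)`.
#' @export
default_predictor_spec <- function() {
  list(
    list(name = "age_years", kind = "numeric"),
    list(name = "prescribed_mme", kind = "numeric"),
    list(name = "discharge_day_mme", kind = "numeric"),
    list(name = "opioid_drugs_prescribed", kind = "numeric"),
    list(name = "preop_assessment", kind = "numeric"),
    list(name = "sex", kind = "categorical",
         levels = c("female", "male"), reference = "female"),
    list(name = "race", kind = "categorical",
         levels = c("White", "Asian", "Black", "Hispanic", "Other"),
         reference = "White"),
    list(name = "tobacco_use", kind = "categorical",
         levels = c("never", "past_month", "months_1_12", "history"),
         reference = "never"),
    list(name = "alcohol_use", kind = "categorical",
         levels = c("never", "occasionally", "daily"), reference = "never"),
    list(name = "asa_class", kind = "categorical",
         levels = c("1", "2", "3", "4-5"), reference = "2"),
    list(name = "los_category", kind = "categorical",
         levels = c("outpatient", "1-2 days", "3-15 days"),
         reference = "outpatient"))
}

#' Build the numeric design matrix with missingness mask
#'
#' Encodes the listed predictors into a numeric matrix: numeric columns pass
#' through, categorical columns become k-1 treatment indicators against their
#' stated reference level. Missing cells are masked (`NA` in the matrix plus
#' a logical mask), never zero-filled; all indicators of a categorical value
#' share the parent's missingness. Column order is deterministic (spec
#' order).
#'
#' @param records patient table.
#' @param predictor_spec list as in [default_predictor_spec()].
#' @return A `covmat` object: list with `x` (numeric matrix, `NA` where
#'   missing), `mask` (logical matrix, `TRUE` = missing), `kind` (per-column
#'   `"numeric"`/`"indicator"`), `parent` (per-column source predictor) and
#'   `row_ids`.
#' @export
build_design_matrix <- function(records, predictor_spec = default_predictor_spec()) {
  cols <- list(); kinds <- character(0); parents <- character(0)
  for (ps in predictor_spec) {
    if (!ps$name %in% names(records))
      stop(sprintf("predictor '%s' absent from records", ps$name), call. = FALSE)
    v <- records[[ps$name]]
    if (ps$kind == "numeric") {
      cols[[ps$name]] <- as.numeric(v)
      kinds <- c(kinds, "numeric"); parents <- c(parents, ps$name)
    } else {
      obs <- !is.na(v)
      bad <- setdiff(unique(v[obs]), ps$levels)
      if (length(bad))
        stop(sprintf("unseen level(s) %s in column '%s'",
                     paste(sQuote(bad), collapse = ", "), ps$name),
             call. = FALSE)
      for (lvl in setdiff(ps$levels, ps$reference)) {
        nm <- paste0(ps$name, "=", lvl)
        col <- as.numeric(v == lvl)
        col[!obs] <- NA
        cols[[nm]] <- col
        kinds <- c(kinds, "indicator"); parents <- c(parents, ps$name)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  structure(list(x = x, mask = is.na(x), kind = kinds, parent = parents,
                 row_ids = records$patient_id %||% seq_len(nrow(x))),
            class = "covmat")
}

#' @export
print.covmat <- function(x, ...) {
  cat(sprintf("<covmat> %d x %d (%.1f%% cells missing)\n",
              nrow(x$x), ncol(x$x), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.covmat <- function(x) dim(x$x)
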