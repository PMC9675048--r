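#' Parameters of the synthetic surgical cohort generator
#'
#' Builds the full parameter set describing the data-generating process for a
#' synthetic post-surgical cohort: marginal covariate distributions, the
#' procedure mix with typical prescription sizes, a logistic survey-response
#' model, a zero-inflated Beta consumption model bounded by prescription size,
#' and a covariate-missingness specification. Defaults are calibrated to the
#' marginal distributions of a single-institution SMS-to-web opioid
#' consumption survey (about 29% of patients prescribed no opioids, about
#' 20.5% overall survey response, response driven by age, tobacco use and
#' in-hospital opioid dose).
#'
#' @param n_patients number of patients to simulate.
#' @param zero_rx_fraction probability of no opioid prescription at discharge.
#' @param response_rate_target overall survey response rate the default
#'   intercept is calibrated to (informational; the intercept itself is
#'   `response_intercept`).
#' @param procedure_mix data.frame with columns `label`, `weight`,
#'   `typical_rx_mme`; weights must sum to 1.
#' @param covariate_spec list of marginal distributions (see Details).
#' @param response_coefficients named list of named numeric vectors giving
#'   log-odds effects of (binned) covariates on survey response. An empty
#'   list makes response independent of covariates.
#' @param response_intercept log-odds intercept of the response model.
#' @param outcome_model list describing consumption: consumed MMEs equal
#'   prescribed MMEs times a zero-inflated Beta fraction whose mean and
#'   zero-probability depend on covariates (see Details), or a degenerate
#'   `constant_mme`.
#' @param missingness_spec list of masking rules applied by
#'   [inject_missingness()].
#' @param seed integer root seed; all stages derive sub-streams from it.
#'
#' @details
#' The consumption model is `consumed = prescribed * B` with
#' `B = 0` with probability `plogis(zero_intercept + zero effects)` and
#' otherwise `B ~ Beta(mu * phi, (1 - mu) * phi)`,
#' `mu = plogis(mean_intercept + mean effects)`. This guarantees the support
#' constraint `0 <= consumed <= prescribed`, right skew, and a point mass at
#' zero. Effects are keyed by derived categorical columns (`age_bin`,
#' `tobacco_use`, `ddmme_bin`, ...), so the true outcome and response models
#' are functions of discrete covariates and can be matched exactly by
#' saturated learners in simulation studies.
#'
#' @return An object of class `cohort_params`.
#' @seealso [generate_cohort()], [true_quantile()]
#' @export
cohort_params <- function(n_patients = 6553,
                          zero_rx_fraction = 0.291,
                          response_rate_target = 0.205,
                          procedure_mix = default_procedure_mix(),
                          covariate_spec = default_covariate_spec(),
                          response_coefficients = default_response_coefficients(),
                          response_intercept = NULL,
                          outcome_model = default_outcome_model(),
                          missingness_spec = default_missingness_spec(),
                          seed = 1L) {
  check_prob(zero_rx_fraction, "zero_rx_fraction")
  check_prob(response_rate_target, "response_rate_target")
  if (!is.data.frame(procedure_mix) ||
      !all(c("label", "weight", "typical_rx_mme") %in% names(procedure_mix)))
    stop_field("procedure_mix", "needs columns label, weight, typical_rx_mme")
  if (abs(sum(procedure_mix$weight) - 1) > 1e-8)
    stop_field("procedure_mix", "weights must sum to 1")
  check_nonneg(procedure_mix$typical_rx_mme, "procedure_mix$typical_rx_mme")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_field("seed", "must be a single integer")
  if (is.null(response_intercept))
    response_intercept <- .default_response_intercept
  p <- list(n_patients = as.integer(n_patients),
            zero_rx_fraction = zero_rx_fraction,
            response_rate_target = response_rate_target,
            procedure_mix = procedure_mix,
            covariate_spec = covariate_spec,
            response_coefficients = response_coefficients,
            response_intercept = response_intercept,
            outcome_model = outcome_model,
            missingness_spec = missingness_spec,
            seed = as.integer(seed))
  class(p) <- "cohort_params"
  p
}

#' @rdname cohort_params
#' @export
default_procedure_mix <- function() {
  data.frame(
    label = c("spinal fusion/laminectomy", "ACDF", "microdiscectomy",
              "sternotomy", "reduction mammoplasty", "inguinal hernia repair",
              "cholecystectomy", "laparoscopic appendectomy",
              "carpal tunnel release", "thyroidectomy"),
    weight = c(0.16, 0.07, 0.07, 0.12, 0.08, 0.12, 0.13, 0.10, 0.08, 0.07),
    typical_rx_mme = c(450, 300, 225, 300, 150, 75, 75, 60, 45, 40),
    stringsAsFactors = FALSE)
}

#' @rdname cohort_params
#' @export
default_covariate_spec <- function() {
  list(
    age = list(edges = c(18, 46, 61, 71, 96),
               probs = c(0.240, 0.319, 0.261, 0.180)),
    sex = c(female = 0.522, male = 0.478),
    race = c(White = 0.729, Asian = 0.026, Black = 0.111,
             Hispanic = 0.019, Other = 0.115),
    tobacco_use = c(never = 0.549, past_month = 0.092,
                    months_1_12 = 0.030, history = 0.329),
    alcohol_use = c(never = 0.284, occasionally = 0.632, daily = 0.084),
    asa_class = c(`1` = 0.080, `2` = 0.492, `3` = 0.350, `4-5` = 0.078),
    los_category = c(outpatient = 0.417, `1-2 days` = 0.311,
                     `3-15 days` = 0.271),
    preop_assessment_rate = 0.865,
    drugs_given_rx = c(`1` = 0.969, `2` = 0.025, `3` = 0.006),
    rx_lnorm_sd = 0.55,
    discharge_zero_prob = c(outpatient = 0.90, `1-2 days` = 0.45,
                            `3-15 days` = 0.35),
    start_month = "2019-03",
    n_months = 20L,
    rx_drift = 0)
}

#' @rdname cohort_params
#' @export
default_response_coefficients <- function() {
  list(
    age_bin = c(`18-45` = -0.32, `46-60` = 0.08, `61-70` = 0.28,
                `71-95` = -0.18),
    race = c(White = 0.12, Asian = -0.10, Black = -0.65, Hispanic = -0.70,
             Other = -0.30),
    tobacco_use = c(never = 0.07, past_month = -0.50, months_1_12 = -0.03,
                    history = 0.15),
    alcohol_use = c(never = -0.18, occasionally = 0.09, daily = 0.42),
    los_category = c(outpatient = -0.05, `1-2 days` = 0.15,
                     `3-15 days` = -0.09),
    asa_class = c(`1` = -0.17, `2` = 0.12, `3` = -0.12, `4-5` = -0.10),
    preop_assessment = c(`1` = 0, `0` = -0.38),
    ddmme_bin = c(`0` = -0.01, `1-10` = 0.07, `>10` = -0.12))
}

#' @rdname cohort_params
#' @export
default_outcome_model <- function() {
  list(
    mean_intercept = -0.35,
    mean_coefficients = list(
      age_bin = c(`18-45` = 0.60, `46-60` = 0.20, `61-70` = -0.25,
                  `71-95` = -0.60),
      tobacco_use = c(never = -0.25, past_month = 0.90, months_1_12 = 0.50,
                      history = 0.15),
      ddmme_bin = c(`0` = -0.60, `1-10` = 0.30, `>10` = 1.00)),
    precision = 2.5,
    zero_intercept = -1.0,
    zero_coefficients = list(
      ddmme_bin = c(`0` = 0.8, `1-10` = -0.2, `>10` = -0.6),
      tobacco_use = c(never = 0.15, past_month = -0.7, months_1_12 = -0.4,
                      history = 0),
      age_bin = c(`18-45` = -0.2, `46-60` = 0, `61-70` = 0.2, `71-95` = 0.5)),
    constant_mme = NULL)
}

#' @rdname cohort_params
#' @export
default_missingness_spec <- function() {
  list(preop_block = list(columns = c("tobacco_use", "alcohol_use"),
                          mechanism = "flag", flag = "preop_assessment",
                          rate = 0.135))
}

# intercept giving ~20.5% overall response under the default coefficients
# (calibrated once by large-sample simulation; see methods vignette)
.default_response_intercept <- -1.3976

# ---------------------------------------------------------------------------

# derived categorical columns used by the response/outcome coefficient lists
derive_bins <- function(records) {
  records$age_bin <- cut(records$age_years, breaks = c(18, 46, 61, 71, 96),
                         labels = c("18-45", "46-60", "61-70", "71-95"),
                         right = FALSE, include.lowest = TRUE)
  records$rx_bin <- cut(records$prescribed_mme, breaks = c(-Inf, 1, 100, 300, Inf),
                        labels = c("0", "1-99", "100-299", "300+"), right = FALSE)
  records$ddmme_bin <- cut(records$discharge_day_mme,
                           breaks = c(-Inf, 1, 11, Inf),
                           labels = c("0", "1-10", ">10"), right = FALSE)
  records
}

# sum named coefficient lists over the matching (derived) columns
coef_linpred <- function(records, coefs) {
  lp <- numeric(nrow(records))
  if (length(coefs) == 0L) return(lp)
  rec <- derive_bins(records)
  for (nm in names(coefs)) {
    if (!nm %in% names(rec))
      stop_field(nm, "coefficient refers to an unknown covariate")
    v <- coefs[[nm]]
    lvl <- as.character(rec[[nm]])
    eff <- unname(v[lvl])
    eff[is.na(eff)] <- 0
    lp <- lp + eff
  }
  lp
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

draw_covariates <- function(n, params) {
  cs <- params$covariate_spec
  bin_idx <- sample.int(length(cs$age$probs), n, replace = TRUE,
                        prob = cs$age$probs)
  lo <- cs$age$edges[bin_idx]
  hi <- cs$age$edges[bin_idx + 1L] - 1L
  age <- floor(runif(n, lo, hi + 1L))
  months <- format(seq(as.Date(paste0(cs$start_month, "-01")),
                       by = "month", length.out = cs$n_months), "%Y-%m")
  data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    procedure_group = sample(params$procedure_mix$label, n, replace = TRUE,
                             prob = params$procedure_mix$weight),
    discharge_month = sample(months, n, replace = TRUE),
    age_years = age,
    sex = sample_cat(n, cs$sex),
    race = sample_cat(n, cs$race),
    tobacco_use = sample_cat(n, cs$tobacco_use),
    alcohol_use = sample_cat(n, cs$alcohol_use),
    asa_class = sample_cat(n, cs$asa_class),
    los_category = sample_cat(n, cs$los_category),
    preop_assessment = as.integer(runif(n) < cs$preop_assessment_rate),
    stringsAsFactors = FALSE)
}

draw_prescription <- function(records, params) {
  n <- nrow(records)
  cs <- params$covariate_spec
  has_rx <- runif(n) >= params$zero_rx_fraction
  drugs <- integer(n)
  drugs[has_rx] <- as.integer(sample_cat(sum(has_rx), cs$drugs_given_rx))
  typical <- params$procedure_mix$typical_rx_mme[
    match(records$procedure_group, params$procedure_mix$label)]
  month_idx <- match(records$discharge_month,
                     sort(unique(records$discharge_month)))
  drift <- 1 + (cs$rx_drift %||% 0) * (month_idx - 1)
  mme <- numeric(n)
  mme[has_rx] <- rlnorm(sum(has_rx), meanlog = log(typical[has_rx] *
                        pmax(drift[has_rx], 0.05)), sdlog = cs$rx_lnorm_sd)
  # pill-discrete: round to 7.5 MME (one 5 mg oxycodone tablet)
  mme[has_rx] <- pmax(round(mme[has_rx] / 7.5) * 7.5, 7.5)
  records$opioid_drugs_prescribed <- drugs
  records$prescribed_mme <- mme

  pz <- cs$discharge_zero_prob[records$los_category]
  dd <- ifelse(runif(n) < pz, 0, round(rgamma(n, shape = 1.5, scale = 6)) + 1)
  records$discharge_day_mme <- as.numeric(dd)
  records
}

draw_response <- function(records, params) {
  lp <- params$response_intercept +
    coef_linpred(records, params$response_coefficients)
  records$responded <- as.integer(runif(nrow(records)) < plogis(lp))
  records
}

# latent consumption for every patient (truncation to [0, prescribed] is
# structural: consumed = prescribed * fraction)
draw_consumption <- function(records, params) {
  om <- params$outcome_model
  n <- nrow(records)
  if (!is.null(om$constant_mme)) {
    check_nonneg(om$constant_mme, "outcome_model$constant_mme")
    return(pmin(om$constant_mme, records$prescribed_mme))
  }
  mu <- plogis(om$mean_intercept + coef_linpred(records, om$mean_coefficients))
  p0 <- plogis(om$zero_intercept + coef_linpred(records, om$zero_coefficients))
  phi <- om$precision
  frac <- rbeta(n, mu * phi, (1 - mu) * phi)
  frac[runif(n) < p0] <- 0
  records$prescribed_mme * frac
}

#' Generate a synthetic surgical cohort
#'
#' Simulates one patient table from the data-generating process described by
#' a [cohort_params()] object: EHR covariates, opioid prescription, survey
#' response drawn from a logistic model, and post-discharge consumption drawn
#' from the bounded zero-inflated Beta outcome model. Patients with no opioid
#' prescription have consumption measured (zero) regardless of response.
#'
#' The latent consumption of every patient (including nonrespondents) is kept
#' in the `"latent_consumed"` attribute for oracle comparisons; the
#' `consumed_mme` column is only populated where `measured == 1`.
#'
#' @param params a [cohort_params()] object.
#' @return A data.frame of patient records (one row per patient) satisfying
#'   the record invariants: `prescribed_mme == 0` iff
#'   `opioid_drugs_prescribed == 0`; `responded` implies `measured`;
#'   zero prescription implies `measured` and `consumed_mme == 0`;
#'   `consumed_mme <= prescribed_mme` wherever present.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients

  set.seed(substream_seed(params$seed, "covariates"))
  records <- draw_covariates(n, params)
  set.seed(substream_seed(params$seed, "prescription"))
  records <- draw_prescription(records, params)
  set.seed(substream_seed(params$seed, "response"))
  records <- draw_response(records, params)
  set.seed(substream_seed(params$seed, "outcome"))
  latent <- draw_consumption(records, params)

  records$measured <- as.integer(records$responded == 1L |
                                 records$prescribed_mme == 0)
  records$consumed_mme <- ifelse(records$measured == 1L, latent, NA_real_)
  records$consumed_mme[records$prescribed_mme == 0] <- 0
  latent[records$prescribed_mme == 0] <- 0
  attr(records, "latent_consumed") <- latent
  records
}

#' Mask covariate cells according to a missingness specification
#'
#' Applies per-column or block missingness to a cohort table. Block rules set
#' all their columns to missing together (e.g. the preoperative-assessment
#' block masks tobacco and alcohol jointly). Outcome and flag columns
#' (`consumed_mme`, `responded`, `measured`, `preop_assessment`) may never be
#' masked.
#'
#' @param records cohort table.
#' @param missingness_spec list of rules; each rule has `columns`, `rate`,
#'   and `mechanism` (`"mcar"` for independent Bernoulli masking, `"flag"` to
#'   mask rows where the named 0/1 `flag` column is 0).
#' @param seed integer seed.
#' @return `records` with masked cells set to `NA`.
#' @export
inject_missingness <- function(records, missingness_spec, seed = 1L) {
  protected <- c("consumed_mme", "responded", "measured", "preop_assessment",
                 "patient_id")
  set.seed(substream_seed(seed, "missingness"))
  for (rule_name in names(missingness_spec)) {
    rule <- missingness_spec[[rule_name]]
    cols <- rule$columns
    if (!all(cols %in% names(records)))
      stop_field(rule_name, paste("unknown column(s):",
                 paste(setdiff(cols, names(records)), collapse = ", ")))
    if (any(cols %in% protected))
      stop_field(rule_name, "outcome/flag columns may not be masked")
    check_prob(rule$rate %||% 0, paste0(rule_name, "$rate"))
    mech <- rule$mechanism %||% "mcar"
    mask <- if (mech == "flag") {
      records[[rule$flag]] == 0
    } else {
      runif(nrow(records)) < rule$rate
    }
    for (cl in cols) records[[cl]][mask] <- NA
  }
  records
}

#' True consumption quantile of the data-generating process
#'
#' Computes the quantile of the (latent) consumption distribution implied by
#' a parameter set by large-sample Monte Carlo, independent of the
#' nonresponse mechanism. This is the oracle against which the
#' nonresponse-adjusted estimator is validated.
#'
#' @param params a [cohort_params()] object.
#' @param level quantile level in (0, 1).
#' @param subpopulation `"prescribed"` (patients with a nonzero opioid
#'   prescription; the default estimand population) or `"all"`.
#' @param n_mc Monte-Carlo sample size (default 1e6).
#' @return The true quantile in MMEs.
#' @export
true_quantile <- function(params, level, subpopulation = c("prescribed", "all"),
                          n_mc = 1e6) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.numeric(level) || any(level <= 0) || any(level >= 1))
    stop_field("level", "must lie in (0, 1)")
  subpopulation <- match.arg(subpopulation)
  big <- params
  big$n_patients <- as.integer(n_mc)
  set.seed(substream_seed(params$seed, "oracle-covariates"))
  rec <- draw_covariates(big$n_patients, big)
  set.seed(substream_seed(params$seed, "oracle-prescription"))
  rec <- draw_prescription(rec, big)
  set.seed(substream_seed(params$seed, "oracle-outcome"))
  y <- draw_consumption(rec, big)
  y[rec$prescribed_mme == 0] <- 0
  if (subpopulation == "prescribed") y <- y[rec$prescribed_mme > 0]
  vapply(level, function(p) quantile_type1(y, p), numeric(1))
}

#' Write / read a cohort table as delimited text
#'
#' @param records cohort data.frame.
#' @param path file path (comma-separated, header row, ISO month strings).
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(records, path) {
  data.table::fwrite(data.table::as.data.table(records), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE,
                          na.strings = c("", "NA"))
  for (cl in intersect(c("patient_id", "discharge_month"), names(dt)))
    dt[[cl]] <- as.character(dt[[cl]])
  dt
}
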