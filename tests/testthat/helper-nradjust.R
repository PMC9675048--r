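# shared test helpers: small cohorts and hand-built record tables

tiny_params <- function(n = 500, seed = 1, ...) {
  cohort_params(n_patients = n, seed = seed, ...)
}

# fully-responding cohort: every patient measured
full_response_params <- function(n = 400, seed = 1) {
  cohort_params(n_patients = n, seed = seed,
                response_coefficients = list(),
                response_intercept = 20)
}

# minimal hand-built record table
make_records <- function(n, prescribed_mme, responded,
                         consumed = NULL, group = "g1") {
  measured <- as.integer(responded == 1L | prescribed_mme == 0)
  if (is.null(consumed)) {
    consumed <- ifelse(measured == 1L, pmin(prescribed_mme, 10), NA_real_)
    consumed[prescribed_mme == 0] <- 0
  }
  data.frame(patient_id = sprintf("T%04d", seq_len(n)),
             procedure_group = group,
             discharge_month = "2019-03",
             age_years = 50, sex = "female", race = "White",
             tobacco_use = "never", alcohol_use = "never",
             asa_class = "2", los_category = "outpatient",
             preop_assessment = 1L,
             opioid_drugs_prescribed = as.integer(prescribed_mme > 0),
             prescribed_mme = prescribed_mme,
             discharge_day_mme = 0,
             responded = as.integer(responded),
             measured = measured,
             consumed_mme = consumed,
             stringsAsFactors = FALSE)
}

# expand a two-level contingency row into patient records
records_from_counts <- function(levels, n, events) {
  do.call(rbind, lapply(seq_along(levels), function(i) {
    data.frame(sex = levels[i],
               responded = rep(c(1L, 0L), c(events[i], n[i] - events[i])),
               prescribed_mme = 100,
               stringsAsFactors = FALSE)
  }))
}
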