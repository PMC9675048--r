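test_that("eligibility filters tally exclusions in order", {
  rec <- make_records(10, prescribed_mme = rep(100, 10), responded = rep(1, 10))
  expect_identical(apply_eligibility(rec, list())$records, rec)
  expect_equal(nrow(apply_eligibility(rec, list())$report), 0)

  rec$age_years <- c(17, rep(50, 9))
  out <- apply_eligibility(rec, list(adult = list(field = "age_years",
                                                  op = ">=", value = 18)))
  expect_equal(nrow(out$records), 9)
  expect_equal(out$report$excluded, 1)

  # planted violations of three sequential rules, recounted by brute force
  set.seed(4)
  n <- 200
  rec <- make_records(n, prescribed_mme = rep(100, n), responded = rep(0, n))
  rec$age_years <- ifelse(seq_len(n) <= 13, 16, 50)
  rec$los_category <- ifelse(seq_len(n) %in% 14:20, "rehab", "outpatient")
  rec$asa_class <- ifelse(seq_len(n) %in% 21:25, "6", "2")
  rules <- list(
    adult = list(field = "age_years", op = ">=", value = 18),
    not_rehab = list(field = "los_category", op = "!=", value = "rehab"),
    valid_asa = list(field = "asa_class", op = "%in%",
                     value = c("1", "2", "3", "4-5")))
  out <- apply_eligibility(rec, rules)
  expect_equal(out$report$excluded, c(13, 7, 5))
  expect_equal(nrow(out$records), n - 25)
  expect_equal(sum(out$report$excluded), nrow(rec) - nrow(out$records))

  expect_error(apply_eligibility(rec, list(x = list(field = "nope",
    op = ">=", value = 1))), "absent field")
})

test_that("pills_to_mme is the product formula with domain checks", {
  expect_equal(pills_to_mme(0, 5, 1.5), 0)
  expect_equal(pills_to_mme(10, 5, 1.5), 75)
  # consumed = prescribed pills - pills remaining, all remaining -> 0 MME
  prescribed_pills <- 20; remaining <- 20
  expect_equal(pills_to_mme(prescribed_pills - remaining, 5, 1.5), 0)
  expect_error(pills_to_mme(-1, 5, 1.5), "pill_count")
  expect_error(pills_to_mme(1, 5, 0), "factor")
  expect_true(all(default_mme_table()$factor > 0))
})

test_that("assign_known_zeros sets zeros, is idempotent, flags conflicts", {
  rec <- make_records(100, prescribed_mme = rep(0, 100),
                      responded = rep(0, 100), consumed = rep(NA_real_, 100))
  rec$measured <- 0L
  out <- assign_known_zeros(rec)
  expect_true(all(out$measured == 1L))
  expect_true(all(out$consumed_mme == 0))
  expect_identical(assign_known_zeros(out), out)

  rec2 <- make_records(5, prescribed_mme = c(0, 0, 100, 100, 100),
                       responded = c(0, 0, 1, 0, 0))
  rec2$consumed_mme[1] <- 30  # inconsistent report
  expect_warning(out2 <- assign_known_zeros(rec2), "nonzero consumption")
  expect_equal(out2$consumed_mme[1], 30)
  expect_true(out2$zero_rx_conflict[1])

  rec3 <- make_records(10, prescribed_mme = rep(50, 10),
                       responded = rep(1, 10))
  expect_identical(assign_known_zeros(rec3)[names(rec3)], rec3)
})

test_that("measurement rate identity holds exactly", {
  # 0.29 zero-rx + 0.71 x 0.21 response among prescribed ~ 0.439
  n <- 10000
  zero <- seq_len(n) <= 2900
  resp <- rep(0L, n)
  resp[!zero][seq_len(round(0.21 * sum(!zero)))] <- 1L
  rec <- make_records(n, prescribed_mme = ifelse(zero, 0, 100),
                      responded = resp)
  rec$measured <- 0L; rec$consumed_mme <- NA_real_
  rec$consumed_mme[rec$responded == 1] <- 5
  out <- assign_known_zeros(rec)
  out$measured[out$responded == 1L] <- 1L
  zf <- mean(out$prescribed_mme == 0)
  rr <- mean(out$responded[out$prescribed_mme > 0])
  expect_equal(mean(out$measured == 1L), zf + (1 - zf) * rr)
  expect_equal(round(zf + (1 - zf) * rr, 2), 0.44)
})

test_that("design matrix encodes per spec with masked missingness", {
  rec <- generate_cohort(tiny_params(n = 300, seed = 2))
  spec1 <- list(list(name = "sex", kind = "categorical",
                     levels = c("female", "male"), reference = "female"))
  cm <- build_design_matrix(rec, spec1)
  expect_equal(ncol(cm$x), 1)
  expect_true(all(cm$x %in% c(0, 1)))

  spec2 <- list(list(name = "race", kind = "categorical",
                     levels = c("White", "Asian", "Black", "Hispanic", "Other"),
                     reference = "White"))
  expect_equal(ncol(build_design_matrix(rec, spec2)$x), 4)

  # count oracle: enumerate the default spec
  spec <- default_predictor_spec()
  expected <- sum(vapply(spec, function(s)
    if (s$kind == "numeric") 1L else length(s$levels) - 1L, integer(1)))
  cm <- build_design_matrix(rec)
  expect_equal(ncol(cm$x), expected)
  expect_identical(cm$mask, is.na(cm$x))

  rec$race[1] <- "Martian"
  expect_error(build_design_matrix(rec, spec2), "Martian")
})

test_that("masked cells propagate to every indicator of the parent", {
  rec <- generate_cohort(tiny_params(n = 500, seed = 3))
  rec <- inject_missingness(rec, default_missingness_spec(), seed = 3)
  cm <- build_design_matrix(rec)
  tob <- which(cm$parent == "tobacco_use")
  expect_gt(length(tob), 1)
  miss_rows <- is.na(rec$tobacco_use)
  for (j in tob) expect_identical(unname(cm$mask[, j]), miss_rows)
})
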