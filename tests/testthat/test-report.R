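est_table <- function(groups, adj, una, level = 0.5) {
  rbind(data.frame(procedure_group = groups, level = level, method = "adjusted",
                   point = adj, ci_low = adj, ci_high = adj,
                   n_total = 100, n_measured = 50),
        data.frame(procedure_group = groups, level = level, method = "unadjusted",
                   point = una, ci_low = una, ci_high = una,
                   n_total = 100, n_measured = 50))
}

test_that("correction summary is the absolute relative change", {
  est <- est_table(c("a", "b"), adj = c(10, 20), una = c(10, 20))
  cs <- correction_summary(est, levels = 0.5)
  expect_equal(unname(cs[["0.5"]]$corrections), c(0, 0))
  expect_equal(cs[["0.5"]]$mean, 0)

  est <- est_table("a", adj = 137, una = 100)
  expect_equal(unname(correction_summary(est, 0.5)[["0.5"]]$corrections), 37)

  planted <- c(0, 7, 37, 65, 80)
  est <- est_table(letters[1:5], adj = 100 + planted, una = rep(100, 5))
  cs <- correction_summary(est, 0.5)
  expect_equal(cs[["0.5"]]$mean, mean(planted))
  expect_equal(cs[["0.5"]]$iqr,
               unname(quantile(planted, c(0.25, 0.75))))

  # zero unadjusted -> undefined, excluded from the mean
  est <- est_table(c("a", "b"), adj = c(5, 110), una = c(0, 100))
  cs <- correction_summary(est, 0.5)
  expect_equal(cs[["0.5"]]$undefined, "a")
  expect_equal(cs[["0.5"]]$mean, 10)

  bad <- est_table("a", 1, 1)
  bad$procedure_group[bad$method == "unadjusted"] <- "zzz"
  expect_error(correction_summary(bad, 0.5), "zzz")

  # invariance to group ordering
  est <- est_table(letters[1:4], adj = c(12, 30, 7, 90), una = c(10, 20, 14, 80))
  shuffled <- est[c(3, 1, 4, 2, 7, 5, 8, 6), ]
  expect_equal(correction_summary(est, 0.5)[["0.5"]]$mean,
               correction_summary(shuffled, 0.5)[["0.5"]]$mean)
})

test_that("reference comparison tallies closer/farther/unchanged", {
  ref <- data.frame(procedure_group = c("a", "b"), level = 0.5,
                    point = c(12, 50))
  est <- est_table(c("a", "b"), adj = c(10, 30), una = c(20, 30))
  cc <- compare_reference(est, ref, 0.5)[["0.5"]]
  expect_equal(unname(cc$verdicts["a"]), "closer")  # |10-12| < |20-12|
  expect_equal(unname(cc$verdicts["b"]), "unchanged")
  expect_equal(cc$tally, "1/2")

  est2 <- est_table(c("a", "b"), adj = c(12, 50), una = c(20, 30))
  cc2 <- compare_reference(est2, ref, 0.5)[["0.5"]]
  expect_equal(cc2$closer, 2)

  est3 <- est_table(c("a", "b", "c"), adj = c(1, 2, 3), una = c(4, 5, 6))
  expect_message(cc3 <- compare_reference(est3, ref, 0.5), "c")
  expect_equal(cc3[["0.5"]]$n, 2)
})

test_that("prescription gap ratios match brute-force quantile division", {
  rec <- make_records(50, prescribed_mme = rep(100, 50), responded = rep(1, 50),
                      consumed = rep(100, 50))
  g <- prescription_gap(rec, by_group = FALSE)
  expect_true(all(g$ratio_pct == 100))
  expect_true(all(g$unconsumed_pct == 0))

  rec$consumed_mme <- 0
  g0 <- prescription_gap(rec, by_group = FALSE)
  expect_true(all(g0$ratio_pct == 0))
  expect_true(all(g0$unconsumed_pct == 100))

  set.seed(1)
  rec2 <- make_records(400, prescribed_mme = round(rlnorm(400, 4, 0.5)),
                       responded = rep(1, 400))
  rec2$consumed_mme <- rec2$prescribed_mme * runif(400)
  g2 <- prescription_gap(rec2, by_group = FALSE)
  m <- rec2[rec2$measured == 1 & rec2$prescribed_mme > 0, ]
  for (i in seq_len(nrow(g2))) {
    lv <- g2$level[i]
    expect_equal(g2$ratio_pct[i],
                 100 * quantile(m$consumed_mme, lv, type = 1) /
                   quantile(m$prescribed_mme, lv, type = 1),
                 ignore_attr = TRUE)
  }
})

test_that("rolling quantile trend windows behave", {
  rec <- generate_cohort(tiny_params(n = 8000, seed = 18))
  gp <- names(sort(table(rec$procedure_group), decreasing = TRUE))[1]
  months <- length(unique(rec$discharge_month))
  whole <- rolling_quantile_trend(rec, gp, level = 0.75,
                                  window_months = months, min_n = 5)
  d <- rec[rec$procedure_group == gp & rec$measured == 1 &
             rec$prescribed_mme > 0, ]
  expect_equal(whole$quantile_mme[nrow(whole)],
               quantile(d$consumed_mme, 0.75, type = 1), ignore_attr = TRUE)
  expect_error(rolling_quantile_trend(rec, "nope"), "unknown")

  cs <- default_covariate_spec(); cs$rx_drift <- -0.04
  p <- cohort_params(n_patients = 30000, seed = 19, covariate_spec = cs)
  drift <- generate_cohort(p)
  gp2 <- names(sort(table(drift$procedure_group), decreasing = TRUE))[1]
  tr <- rolling_quantile_trend(drift, gp2, level = 0.75, window_months = 3,
                               min_n = 10)
  slope <- coef(lm.fit(cbind(1, seq_len(nrow(tr))), tr$quantile_mme))[2]
  expect_lt(slope, 0)
})

test_that("render_report writes the full seven-file bundle deterministically", {
  rec <- generate_cohort(tiny_params(n = 2500, seed = 20))
  est <- est_table(c("a", "b"), adj = c(10, 30), una = c(12, 28))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- render_report(list(records = rec, estimates = est), d1, seed = 20)
  p2 <- render_report(list(records = rec, estimates = est), d2, seed = 20)
  expect_length(p1, 7)
  expect_true(all(file.exists(p1)))
  for (i in seq_along(p1))
    if (!grepl("manifest", p1[i]))
      expect_identical(readLines(p1[i]), readLines(p2[i]))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 20)
  expect_length(man$files, 7)
})
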