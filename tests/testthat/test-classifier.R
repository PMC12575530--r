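calib_frame <- function(cancer_hm = c(0.9, 0.8, 0.7, 0.6, 0.1),
                        control_dp = c(0.010, 0.015, 0.019)) {
  rbind(
    data.frame(case_id = paste0("ca", seq_along(cancer_hm)), label = "cancer",
               heatmap_max = cancer_hm, dp_p90 = 0.05),
    data.frame(case_id = paste0("co", seq_along(control_dp)), label = "control",
               heatmap_max = 0.05, dp_p90 = control_dp))
}

test_that("threshold calibration realizes the stated rules", {
  thr <- calibrate_thresholds(calib_frame())
  # 4/5 cancers must exceed the mass threshold: midpoint of 0.6 and 0.1
  expect_equal(thr$heatmap_thr, 0.35)
  expect_equal(thr$provenance$achieved_mass_sensitivity, 0.8)
  # D/P threshold = max of control scores; strict ">" keeps all negative
  expect_equal(thr$dp_thr, 0.019)
  expect_equal(thr$provenance$achieved_dp_specificity, 1)
  expect_true(all(calib_frame()$dp_p90[6:8] <= thr$dp_thr))
})

test_that("calibration invariants hold for arbitrary score sets", {
  set.seed(42)
  for (rep in 1:10) {
    df <- data.frame(
      case_id = sprintf("c%02d", 1:30),
      label = rep(c("cancer", "control"), each = 15),
      heatmap_max = runif(30), dp_p90 = runif(30, 0, 0.2))
    thr <- calibrate_thresholds(df)
    cancers <- df[df$label == "cancer", ]
    controls <- df[df$label == "control", ]
    expect_gte(mean(cancers$heatmap_max > thr$heatmap_thr), 0.80)
    expect_equal(mean(controls$dp_p90 <= thr$dp_thr), 1)
  }
})

test_that("degenerate calibration sets are rejected", {
  expect_error(calibrate_thresholds(calib_frame()[0, ]), "empty")
  one_class <- calib_frame()[1:5, ]
  expect_error(calibrate_thresholds(one_class), "both")
  zeros <- calib_frame(cancer_hm = rep(0, 5))
  expect_error(calibrate_thresholds(zeros), "unattainable")
})

test_that("disjunction verdicts use strict thresholds and localize correctly", {
  thr <- structure(list(heatmap_thr = 0.051, dp_thr = 0.019),
                   class = "dp_thresholds")
  r1 <- classify_case(list(case_id = "a", heatmap_max = 0.06, dp_p90 = 0.010,
                           mass_segment = "head", mass_fraction = 0.2), thr)
  expect_equal(r1$verdict, "positive")
  expect_equal(r1$fired_channels, "mass")
  expect_equal(r1$localization_source, "mass")
  expect_equal(r1$segment, "head")

  # boundary equality on both channels is negative under strict ">"
  r2 <- classify_case(list(heatmap_max = 0.051, dp_p90 = 0.019), thr)
  expect_equal(r2$verdict, "negative")
  expect_equal(r2$localization_source, "none")

  # indirect-indicator save: mass silent, D/P fires and localizes
  r3 <- classify_case(list(heatmap_max = 0.02, dp_p90 = 0.030,
                           dp_segment = "body", dp_fraction = 0.55), thr)
  expect_equal(r3$verdict, "positive")
  expect_equal(r3$fired_channels, "dp")
  expect_equal(r3$localization_source, "dp")
  expect_equal(r3$segment, "body")

  # missing channel: warning, treated as not fired
  expect_warning(r4 <- classify_case(list(heatmap_max = NA, dp_p90 = 0.030), thr),
                 "missing heatmap")
  expect_equal(r4$verdict, "positive")
  expect_false(r4$mass_fired)
})

test_that("cohort classification obeys the disjunction identities", {
  set.seed(7)
  n <- 60
  df <- data.frame(case_id = sprintf("c%02d", 1:n),
                   label = sample(c("cancer", "control"), n, replace = TRUE,
                                  prob = c(0.5, 0.5)),
                   heatmap_max = runif(n), dp_p90 = runif(n, 0, 0.2))
  thr <- structure(list(heatmap_thr = 0.5, dp_thr = 0.1),
                   class = "dp_thresholds")
  out <- classify_cohort(df, thr)
  res <- out$results
  # combined positives = union of channel positives
  expect_identical(res$verdict == "positive", res$mass_fired | res$dp_fired)
  sens <- function(ct) ct$tp / (ct$tp + ct$fn)
  spec <- function(ct) ct$tn / (ct$tn + ct$fp)
  expect_gte(sens(out$summary$combined),
             max(sens(out$summary$mass), sens(out$summary$dp)))
  expect_lte(spec(out$summary$combined),
             min(spec(out$summary$mass), spec(out$summary$dp)))

  # a vacuous D/P channel reduces the disjunction to the mass channel
  df0 <- df; df0$dp_p90 <- 0
  out0 <- classify_cohort(df0, thr)
  expect_identical(out0$results$verdict == "positive", out0$results$mass_fired)

  # raising either threshold never converts a negative into a positive
  thr_hi <- structure(list(heatmap_thr = 0.7, dp_thr = 0.15),
                      class = "dp_thresholds")
  res_hi <- classify_cohort(df, thr_hi)$results
  was_negative <- res$verdict == "negative"
  expect_true(all(res_hi$verdict[was_negative] == "negative"))

  expect_error(classify_cohort(rbind(df, df[1, ]), thr), "duplicate")
})

test_that("thresholds persist through JSON round-trip", {
  thr <- calibrate_thresholds(calib_frame())
  f <- tempfile(fileext = ".json")
  write_thresholds_json(thr, f)
  back <- read_thresholds_json(f)
  expect_equal(back$heatmap_thr, thr$heatmap_thr)
  expect_equal(back$dp_thr, thr$dp_thr)
  expect_equal(back$provenance$achieved_dp_specificity, 1)
})
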