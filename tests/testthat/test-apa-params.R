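test_that("phase durations follow the event arithmetic exactly", {
  ev <- gait_events(8.40, 8.80, 9.10, 9.60, source = "force_plate")
  d <- compute_durations(ev)
  expect_equal(unname(d), c(0.40, 0.30, 0.70, 0.50, 1.20), tolerance = 1e-12)
  expect_equal(d[["dur_apa"]], d[["dur_imbalance"]] + d[["dur_unloading"]])
  expect_equal(d[["dur_step"]], d[["dur_apa"]] + d[["dur_swing"]])
  # zero-length imbalance is legal
  d0 <- compute_durations(gait_events(8.4, 8.4, 9.1, 9.6, source = "imu"))
  expect_equal(d0[["dur_imbalance"]], 0)
})

test_that("phase amplitudes are signal differences at the event samples", {
  fs <- 100
  t <- (0:300) / fs
  ml <- approx(c(0, 1.0, 1.5, 3), c(0, 0, 2.2, -7.2), xout = t)$y
  ap <- approx(c(0, 1.0, 1.5, 3), c(0, 0, -2.0, -1.0), xout = t)$y
  ev <- gait_events(1.0, 1.5, 3.0, 3.0, source = "force_plate")
  a <- compute_amplitudes(time_series(ml, fs = fs), time_series(ap, fs = fs),
                          ev)
  expect_equal(a[["amp_imbalance_ml"]], 2.2, tolerance = 1e-6)
  expect_equal(a[["amp_unloading_ml"]], -9.4, tolerance = 1e-6)
  expect_equal(a[["amp_imbalance_ap"]], -2.0, tolerance = 1e-6)
  # flat signal -> zero amplitudes
  flat <- time_series(rep(1, 301), fs = fs)
  a0 <- compute_amplitudes(flat, flat, ev)
  expect_true(all(a0 == 0))
  # event outside the record
  bad <- gait_events(1.0, 1.5, 9.0, 9.9, source = "force_plate")
  expect_error(compute_amplitudes(time_series(ml, fs = fs),
                                  time_series(ap, fs = fs), bad),
               class = "apa_range_error")
})

test_that("trial averaging is a per-subject mean within one test", {
  base <- expand.grid(subject = c("s1", "s1", "s1"), stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(c(0.18, 0.20, 0.19), function(v) {
    ev <- gait_events(10, 10.4, 10.7, 11.2, source = "imu")
    s <- time_series(rep(0, 700), fs = 50)
    out <- trial_summary("s1", "gait_initiation", "imu", ev, s, s)
    out$amp_imbalance_ml <- v
    out
  }))
  avg <- average_trials(rows)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$amp_imbalance_ml, 0.19, tolerance = 1e-12)
  # single trial is the identity
  one <- average_trials(rows[1, ])
  expect_equal(one$amp_imbalance_ml, 0.18)
  # mixing tasks is a grouping error
  mixed <- rows
  mixed$task[2] <- "step_climbing"
  expect_error(average_trials(mixed), class = "apa_grouping_error")
})

test_that("perfectly proportional paired summaries correlate with r = 1", {
  set.seed(5)
  mk <- function(vals, src) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      ev <- gait_events(10, 10.4, 10.7, 11.2, source = src)
      s <- time_series(rep(0, 700), fs = 50)
      out <- trial_summary(sprintf("s%d", i), "gait_initiation", src, ev, s, s)
      out[apakit:::apa_param_names()] <-
        as.list(vals[i] * seq_len(9) + c(0, 0, 0, 0, 0, 1, 1, 1, 1))
      out
    }))
  }
  vals <- rnorm(6, 2, 0.5)
  fp <- mk(vals, "force_plate")
  imu <- mk(1.7 * vals, "imu")
  rep <- validate_against_fp(fp, imu)
  expect_true(all(abs(rep$r - 1) < 1e-9))
  expect_true(all(rep$p < 0.01))
  # zero variance flags a degenerate correlation
  fp2 <- fp
  fp2$dur_swing <- 1
  rep2 <- validate_against_fp(fp2, imu)
  expect_true(rep2$degenerate[rep2$parameter == "dur_swing"])
  expect_error(validate_against_fp(fp[1:2, ], imu[1:2, ]),
               class = "apa_insufficient_data_error")
})

test_that("independent paired summaries show no systematic correlation", {
  set.seed(42)
  mk <- function(src) {
    do.call(rbind, lapply(1:50, function(i) {
      ev <- gait_events(10, 10.4, 10.7, 11.2, source = src)
      s <- time_series(rep(0, 700), fs = 50)
      out <- trial_summary(sprintf("s%02d", i), "gait_initiation", src, ev, s, s)
      out[apakit:::apa_param_names()] <- as.list(rnorm(9))
      out
    }))
  }
  rep <- validate_against_fp(mk("force_plate"), mk("imu"))
  expect_lt(mean(abs(rep$r)), 0.25)
  expect_gt(mean(rep$p), 0.2)
})

test_that("group comparison returns a null effect for identical groups", {
  co <- generate_cohort(4, 1, tasks = "gait_initiation", seed = 71)
  smry <- summarize_imu_cohort(co)
  avg <- average_trials(smry)
  cmp <- compare_groups(avg, avg)
  expect_true(all(abs(cmp$t) < 1e-12))
  expect_true(all(cmp$p > 0.999))
  expect_false(any(cmp$significant))
  paired <- compare_groups(avg, avg, paired = TRUE)
  expect_true(all(paired$t == 0))
  expect_true(all(paired$p == 1))
  expect_error(compare_groups(avg[1, , drop = FALSE], avg),
               class = "apa_insufficient_data_error")
})
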