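test_that("trunk-acceleration onset crosses A times the quiet SD", {
  fs <- 50
  quiet <- rep(c(0.02, -0.02), 200)        # SD ~0.02 m/s^2 over [0, 8)
  hold <- c(rep(c(0.02, -0.02), 12), 0.02) # stays inside the 0.04 threshold
  move <- rep(0.5, 30)
  x <- time_series(c(quiet, hold, move), fs = fs)
  on <- detect_onset_imu(x, c(0, 7.99), A = 2)
  expect_equal(as.numeric(on), 8.50)       # first sample of the excursion
  expect_equal(attr(on, "threshold"), 2 * sd(quiet), tolerance = 1e-6)
  expect_error(detect_onset_imu(time_series(rep(0.3, 500), fs = fs), c(0, 8)),
               class = "apa_degenerate_baseline_error")
})

test_that("gyro landmarks find the two peaks and the zero-crossing", {
  fs <- 50
  t <- (0:149) / fs
  rc <- function(t, t0, t1) {
    u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
    (1 - cos(pi * u)) / 2
  }
  v <- 120 * (rc(t, 0.90, 1.10) - rc(t, 1.10, 1.30)) -
    20 * sin(pi * pmin(pmax((t - 1.30) / 0.10, 0), 1)) +
    90 * (rc(t, 1.40, 1.60) - rc(t, 1.60, 1.80))
  g <- time_series(v, fs = fs, units = "deg/s")
  f <- extract_gyro_features(g, 0.5)
  expect_equal(f$omega_pk, 120)
  expect_equal(f$t_pk1, 1.10)
  expect_equal(f$t_pk2, 1.60)
  expect_equal(f$t_zero_cross, 1.40, tolerance = 1e-9)
  expect_equal(f$sign, 1)
  expect_true(f$t_pk1 < f$t_zero_cross && f$t_zero_cross < f$t_pk2)

  # mirror-mounted sensor: same landmarks after sign normalization
  f2 <- extract_gyro_features(time_series(-v, fs = fs), 0.5)
  expect_equal(f2$omega_pk, 120)
  expect_equal(f2$sign, -1)

  expect_error(extract_gyro_features(time_series(t, fs = fs), 0.5),
               class = "apa_missing_peak_error")
})

test_that("heel-off and toe-off are Omega_pk-relative threshold crossings", {
  fs <- 100
  t <- (0:299) / fs
  v <- ifelse(t < 0.9, 0, pmin(160 * (t - 0.9), 100))  # ramp to 100 deg/s
  g <- time_series(v, fs = fs)
  f <- manual_features(100, t_pk1 = 1.60)
  # H = 0.07 -> threshold 7 deg/s; first sample above at 0.95 s
  expect_equal(detect_heel_off_imu(g, 0.5, f, H = 0.07, interp = FALSE), 0.95)
  # H = 0: first strictly positive sample after onset
  expect_equal(detect_heel_off_imu(g, 0.5, f, H = 0, interp = FALSE), 0.91)

  # falling flank crossing T * Omega_pk
  v2 <- ifelse(t < 1.02, 100, pmax(100 - 255 * (t - 1.02), 0))
  g2 <- time_series(v2, fs = fs)
  f2 <- manual_features(100, t_pk1 = 1.02)
  expect_equal(detect_toe_off_imu(g2, f2, T_ = 0.25, interp = FALSE), 1.32)
  # T = 1: the first sample after the peak already sits below Omega_pk
  expect_equal(detect_toe_off_imu(g2, f2, T_ = 1, interp = FALSE), 1.03)
  expect_error(detect_toe_off_imu(time_series(rep(100, 300), fs = fs), f2, 0.25),
               class = "apa_detection_error")
})

test_that("foot contact is the median point of zero-crossing and second peak", {
  f <- manual_features(100, 1.1, t_pk2 = 1.60, t_zero_cross = 1.40)
  expect_equal(as.numeric(detect_foot_contact_imu(f)), 1.50)
  fd <- manual_features(100, 1.1, t_pk2 = 1.40, t_zero_cross = 1.40)
  out <- detect_foot_contact_imu(fd)
  expect_equal(as.numeric(out), 1.40)
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("detected times are monotone in the threshold factors", {
  tr <- generate_trial(trial_blueprint(seed = 51))
  prep <- apakit:::imu_preprocess(tr$imu)
  qw <- tr$imu$quiet_window
  ons <- sapply(1:5, function(A) {
    as.numeric(detect_onset_imu(prep$acc_ml, qw, A = A, interp = TRUE))
  })
  expect_true(all(diff(ons) >= 0))
  on <- ons[2]
  f <- extract_gyro_features(prep$gyro, on)
  hos <- sapply(seq(0.02, 0.5, by = 0.06), function(H) {
    detect_heel_off_imu(prep$gyro, on, f, H)
  })
  expect_true(all(diff(hos) >= 0))
  tos <- sapply(seq(0.1, 1, by = 0.1), function(T_) {
    detect_toe_off_imu(prep$gyro, f, T_)
  })
  expect_true(all(diff(tos) <= 0))  # larger T crosses closer to the peak
})

test_that("gyro detection is invariant to positive rescaling", {
  tr <- generate_trial(trial_blueprint(seed = 52))
  prep <- apakit:::imu_preprocess(tr$imu)
  on <- as.numeric(detect_onset_imu(prep$acc_ml, tr$imu$quiet_window, A = 2))
  f1 <- extract_gyro_features(prep$gyro, on)
  g2 <- time_series(3.7 * prep$gyro$values, fs = prep$gyro$fs)
  f2 <- extract_gyro_features(g2, on)
  expect_equal(f2$omega_pk, 3.7 * f1$omega_pk)
  expect_equal(detect_heel_off_imu(g2, on, f2, 0.07),
               detect_heel_off_imu(prep$gyro, on, f1, 0.07))
  expect_equal(detect_toe_off_imu(g2, f2, 0.25),
               detect_toe_off_imu(prep$gyro, f1, 0.25))
  expect_equal(as.numeric(detect_foot_contact_imu(f2)),
               as.numeric(detect_foot_contact_imu(f1)))
})

test_that("full inertial detection recovers synthetic events in both modes", {
  for (s in 1:4) {
    task <- if (s %% 2) "gait_initiation" else "step_climbing"
    tr <- generate_trial(trial_blueprint(seed = 200 + s, task = task))
    ev <- detect_all_imu(tr$imu)
    expect_true(ev$apa_onset < ev$heel_off)
    expect_true(ev$heel_off < ev$toe_off)
    expect_true(ev$toe_off < ev$foot_contact)
    err <- abs(unlist(ev[c("apa_onset", "heel_off", "toe_off",
                           "foot_contact")]) -
                 unlist(tr$truth[c("apa_onset", "heel_off", "toe_off",
                                   "foot_contact")]))
    expect_lt(max(err), 0.04)  # two samples at 50 Hz
  }
  # hypometric mode still detects, with a delayed onset crossing
  hc <- generate_trial(trial_blueprint(seed = 300))
  pd <- generate_trial(trial_blueprint(seed = 300, pd_like = TRUE))
  prep_hc <- apakit:::imu_preprocess(hc$imu)
  prep_pd <- apakit:::imu_preprocess(pd$imu)
  on_hc <- detect_onset_imu(prep_hc$acc_ml, hc$imu$quiet_window, A = 2)
  on_pd <- detect_onset_imu(prep_pd$acc_ml, pd$imu$quiet_window, A = 2)
  expect_gte(attr(on_pd, "t_cross"), attr(on_hc, "t_cross"))
  expect_s3_class(detect_all_imu(pd$imu), "apa_events")
})
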