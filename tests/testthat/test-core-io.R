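test_that("time series validate sampling and finiteness", {
  x <- time_series(1:10, fs = 100, t0 = 2, units = "cm")
  expect_equal(ts_times(x)[1], 2)
  expect_equal(ts_times(x)[10], 2 + 9 / 100)
  expect_equal(ts_index(x, 2.051), 6)  # nearest sample (2.05)
  expect_error(time_series(c(1, NA), fs = 10), class = "apa_schema_error")
  expect_error(time_series(1:5, fs = 0), class = "apa_schema_error")
  expect_error(ts_at(x, 5), class = "apa_range_error")
})

test_that("recordings enforce channel alignment and quiet window", {
  mk <- function(n = 2000, fs = 800) time_series(rnorm(n), fs = fs)
  set.seed(1)
  expect_error(
    force_plate_recording(mk(), mk(), mk(), mk(1000), body_weight = 700,
                          quiet_window = c(0, 1.5)),
    class = "apa_schema_error")
  expect_error(
    force_plate_recording(mk(), mk(), mk(), mk(), body_weight = -1,
                          quiet_window = c(0, 1.5)),
    class = "apa_schema_error")
  expect_error(
    force_plate_recording(mk(), mk(), mk(), mk(), body_weight = 700,
                          quiet_window = c(0, 0.5)),
    class = "apa_schema_error")
  rec <- force_plate_recording(mk(), mk(), mk(), mk(), body_weight = 700,
                               quiet_window = c(0, 2))
  expect_s3_class(rec, "apa_fp_recording")
})

test_that("a recording file round-trips bit-exactly with its metadata", {
  tr <- generate_trial(trial_blueprint(seed = 7))
  dir <- withr::local_tempdir()
  fp_path <- file.path(dir, "fp.csv")
  imu_path <- file.path(dir, "imu.csv")
  write_recording(tr$fp, fp_path)
  write_recording(tr$imu, imu_path)
  fp2 <- read_recording(fp_path, "force_plate")
  imu2 <- read_recording(imu_path)  # schema from sidecar
  expect_identical(fp2$cop1_ml$values, tr$fp$cop1_ml$values)
  expect_identical(fp2$fz2$values, tr$fp$fz2$values)
  expect_identical(imu2$shank_gyro_ml$values, tr$imu$shank_gyro_ml$values)
  expect_equal(fp2$body_weight, tr$fp$body_weight)
  expect_equal(fp2$quiet_window, tr$fp$quiet_window)
  expect_equal(imu2$task, tr$imu$task)
  # duration arithmetic: n samples at fs Hz
  expect_equal(length(fp2$cop1_ml$values) / fp2$cop1_ml$fs,
               length(tr$fp$cop1_ml$values) / 800)
})

test_that("reader reports missing channels and bad metadata by name", {
  tr <- generate_trial(trial_blueprint(seed = 8))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fp.csv")
  write_recording(tr$fp, path)
  df <- utils::read.csv(path)
  df$fz2 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  err <- tryCatch(read_recording(path, "force_plate"), error = function(e) e)
  expect_s3_class(err, "apa_schema_error")
  expect_match(conditionMessage(err), "fz2 absent")
  expect_error(read_recording(file.path(dir, "nope.csv")),
               class = "apa_io_error")
})

test_that("stepping-side mirror restores the ML convention on load", {
  tr <- generate_trial(trial_blueprint(seed = 9))
  rec <- tr$fp
  rec$stepping_side <- "left"
  dir <- withr::local_tempdir()
  path <- file.path(dir, "fp.csv")
  write_recording(rec, path)
  # raw file holds the mirrored (sensor-frame) ML channel
  raw <- utils::read.csv(path)
  expect_identical(as.numeric(raw$cop1_ml), -rec$cop1_ml$values)
  back <- read_recording(path)
  expect_identical(back$cop1_ml$values, rec$cop1_ml$values)
})

test_that("events round-trip through JSON and reject bad ordering", {
  ev <- gait_events(0.50, 0.90, 1.20, 1.70, source = "force_plate")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ev.json")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(unclass(back), unclass(ev))

  truth <- generate_trial(trial_blueprint(seed = 3))$truth
  write_events(truth, path)
  back <- read_events(path)
  for (nm in c("apa_onset", "heel_off", "toe_off", "foot_contact",
               "trailing_toe_off")) {
    expect_lt(abs(back[[nm]] - truth[[nm]]), 1e-9)
  }

  bad <- list(apa_onset = 1.0, heel_off = 0.5, toe_off = 1.2,
              foot_contact = 1.5, source = "imu")
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_events(path), class = "apa_integrity_error")
  expect_error(gait_events(1, 0.5, 1.2, 1.5), class = "apa_integrity_error")
})

test_that("threshold sets validate ranges and round-trip as JSON", {
  expect_error(thresholds(-1, 0.1, 0.2), class = "apa_schema_error")
  expect_error(thresholds(2, 1.2, 0.2), class = "apa_schema_error")
  expect_error(thresholds(2, 0.1, 0.2, fc_grf_fraction = 1.5),
               class = "apa_schema_error")
  thr <- list(gait_initiation = default_thresholds("gait_initiation"),
              step_climbing = default_thresholds("step_climbing"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "thr.json")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back$gait_initiation$H, 0.07)
  expect_equal(back$step_climbing$T, 1)
})
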