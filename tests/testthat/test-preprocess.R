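test_that("zero-phase filtering passes DC exactly and preserves timing", {
  x <- time_series(rep(2.5, 400), fs = 800)
  y <- zero_phase_lowpass(x, filter_spec(10))
  expect_lt(max(abs(y$values - 2.5)), 1e-6)

  # a 0.5 Hz sinusoid through a 3.5 Hz filter: peak lag below one sample
  fs <- 50
  t <- (0:599) / fs
  s <- time_series(sin(2 * pi * 0.5 * t), fs = fs)
  y <- zero_phase_lowpass(s, filter_spec(3.5))
  cc <- stats::ccf(y$values, s$values, lag.max = 5, plot = FALSE)
  expect_lte(abs(cc$lag[which.max(cc$acf)]), 1)
})

test_that("stop-band attenuation matches the analytic squared Butterworth magnitude", {
  fs <- 800
  t <- (0:7999) / fs
  x <- time_series(sin(2 * pi * 0.5 * t) + sin(2 * pi * 15 * t), fs = fs)
  y <- zero_phase_lowpass(x, filter_spec(10))
  # amplitude of the 15 Hz component by quadrature regression (edges trimmed)
  mid <- 801:7200
  base <- cbind(sin(2 * pi * 15 * t[mid]), cos(2 * pi * 15 * t[mid]),
                sin(2 * pi * 0.5 * t[mid]), cos(2 * pi * 0.5 * t[mid]))
  cf <- stats::lm.fit(base, y$values[mid])$coefficients
  amp15 <- sqrt(cf[1]^2 + cf[2]^2)
  expected <- apakit:::zero_phase_gain(15, 10, fs, 4)
  expect_lt(abs(amp15 - expected) / expected, 0.02)
  # the in-band component is untouched
  expect_lt(abs(sqrt(cf[3]^2 + cf[4]^2) - 1), 1e-3)
})

test_that("filtering is linear and rejects invalid inputs", {
  set.seed(4)
  x <- time_series(rnorm(300), fs = 100)
  y1 <- zero_phase_lowpass(x, filter_spec(10))
  x3 <- time_series(3 * x$values, fs = 100)
  y3 <- zero_phase_lowpass(x3, filter_spec(10))
  expect_equal(y3$values, 3 * y1$values, tolerance = 1e-12)
  expect_error(zero_phase_lowpass(time_series(1:10, fs = 100), filter_spec(10)),
               class = "apa_length_error")
  expect_error(zero_phase_lowpass(x, filter_spec(60)),
               class = "apa_schema_error")
})

test_that("tilt correction zeroes a statically tilted gravity vector", {
  g <- apakit:::GRAVITY
  n <- 500
  qw <- c(0, 8)
  mk <- function(v) time_series(rep(v, n), fs = 50)
  # perfectly aligned sensor
  out <- tilt_correct(mk(g), mk(0), mk(0), qw)
  expect_lt(max(abs(c(out$trunk_acc_v$values, out$trunk_acc_ml$values,
                      out$trunk_acc_ap$values))), 1e-9)
  # pitched 10 deg, rolled 5 deg: static output < 1e-6 m/s^2
  R <- apakit:::tilt_rotation(10 * pi / 180, 5 * pi / 180)
  m <- t(R) %*% c(g, 0, 0)
  out <- tilt_correct(mk(m[1]), mk(m[2]), mk(m[3]), qw)
  expect_lt(max(abs(c(out$trunk_acc_v$values, out$trunk_acc_ml$values,
                      out$trunk_acc_ap$values))), 1e-6)
  expect_equal(unname(out$angles["theta"]), 10 * pi / 180, tolerance = 1e-9)
})

test_that("tilt correction recovers a dynamic ML oscillation under tilt", {
  g <- apakit:::GRAVITY
  fs <- 50
  t <- (0:599) / fs
  a_ml <- 0.3 * sin(2 * pi * 1.2 * t) * (t > 9)  # movement after the quiet window
  for (tilt in c(5, 15)) {
    R <- apakit:::tilt_rotation(tilt * pi / 180, 0.4 * tilt * pi / 180)
    world <- rbind(g, a_ml, 0)
    sensor <- t(R) %*% world
    out <- tilt_correct(time_series(sensor[1, ], fs = fs),
                        time_series(sensor[2, ], fs = fs),
                        time_series(sensor[3, ], fs = fs), c(0, 8))
    rel_rms <- sqrt(mean((out$trunk_acc_ml$values - a_ml)^2)) /
      sqrt(mean(a_ml^2))
    expect_lt(rel_rms, 0.02)
  }
})

test_that("tilt correction is idempotent and rejects implausible gravity", {
  g <- apakit:::GRAVITY
  set.seed(11)
  n <- 500
  R <- apakit:::tilt_rotation(0.1, 0.05)
  sensor <- t(R) %*% rbind(rep(g, n), rnorm(n, 0, 0.01), rnorm(n, 0, 0.01))
  qw <- c(0, 8)
  out1 <- tilt_correct(time_series(sensor[1, ], fs = 50),
                       time_series(sensor[2, ], fs = 50),
                       time_series(sensor[3, ], fs = 50), qw)
  # re-correcting already-corrected data: re-add gravity first
  out2 <- tilt_correct(
    time_series(out1$trunk_acc_v$values + g, fs = 50),
    out1$trunk_acc_ml, out1$trunk_acc_ap, qw)
  expect_lt(max(abs(out2$angles)), 1e-3)
  expect_equal(out2$trunk_acc_ml$values, out1$trunk_acc_ml$values,
               tolerance = 1e-6)
  expect_error(
    tilt_correct(time_series(rep(0.1, n), fs = 50),
                 time_series(rep(0, n), fs = 50),
                 time_series(rep(0, n), fs = 50), qw),
    class = "apa_calibration_error")
})
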