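# Hand-constructed signals for the force-plate detectors; sample grids
# are chosen so the expected crossing instants fall exactly on samples.

test_that("COP onset is the first sustained 2 SD excursion", {
  fs <- 100
  quiet <- rep(c(0.1, -0.1), 400)          # mean 0, SD ~0.10 cm over [0, 8)
  after <- rep(c(0.1, -0.1), 20)           # stays inside the threshold
  move <- rep(1.5, 60)                     # sustained, confirmed excursion
  x <- time_series(c(quiet, after, move), fs = fs)
  on <- detect_onset_cop(x, c(0, 7.99))
  expect_equal(as.numeric(on), 8.40)
  expect_equal(attr(on, "threshold"), 2 * sd(quiet), tolerance = 1e-6)

  expect_error(detect_onset_cop(time_series(rep(1, 900), fs = fs), c(0, 4)),
               class = "apa_degenerate_baseline_error")
  expect_error(detect_onset_cop(x, c(0, 7.99), abs_threshold = 10),
               class = "apa_no_onset_error")
})

test_that("trailing toe-off is the last frame above the force floor", {
  fs <- 100
  # 700 N until 2.00 s, then a linear drop reaching exactly 45.5 N
  # (6.5 % of 700 N) at 2.20 s, and zero afterwards
  fz1 <- c(rep(700, 201), seq(700, 45.5, length.out = 21)[-1], rep(0, 79))
  x <- time_series(fz1, fs = fs)
  expect_equal(detect_trailing_toe_off(x, 700), 2.20)
  expect_error(detect_trailing_toe_off(time_series(rep(700, 100), fs = fs), 700),
               class = "apa_no_liftoff_error")
})

test_that("toe-off and heel-off sit at the maximal point-to-line distances", {
  fs <- 100
  # path (0,0) -> (2,3) -> (4,0); line L1 through (0,0) and (4,0)
  seg <- function(p, q, n) cbind(seq(p[1], q[1], length.out = n),
                                 seq(p[2], q[2], length.out = n))
  pts <- rbind(seg(c(0, 0), c(2, 3), 101), seg(c(2, 3), c(4, 0), 100)[-1, ])
  path <- cop_path(time_series(pts[, 1], fs = fs),
                   time_series(pts[, 2], fs = fs))
  toe <- detect_toe_off_cop(path, 0, 1.99)
  expect_equal(toe$time, 1.00)             # vertex sample
  expect_equal(toe$d_max, 3)
  expect_false(toe$degenerate)

  # heel-off: path (0,0) -> (2,0) -> (2,3); L2 through (0,0) and (2,3)
  pts2 <- rbind(seg(c(0, 0), c(2, 0), 101), seg(c(2, 0), c(2, 3), 100)[-1, ])
  path2 <- cop_path(time_series(pts2[, 1], fs = fs),
                    time_series(pts2[, 2], fs = fs))
  heel <- detect_heel_off_cop(path2, 0, 1.99)
  expect_equal(heel$time, 1.00)
  expect_equal(heel$d_max, 6 / sqrt(13))

  # collinear path: zero distance everywhere, earliest-sample tie-break
  pts3 <- seg(c(0, 0), c(4, 0), 200)
  path3 <- cop_path(time_series(pts3[, 1], fs = fs),
                    time_series(pts3[, 2], fs = fs))
  deg <- detect_toe_off_cop(path3, 0, 1.99)
  expect_true(deg$degenerate)
  expect_equal(deg$time, 0.01)             # first sample inside the window

  # coincident line endpoints
  flat <- cop_path(time_series(rep(1, 200), fs = fs),
                   time_series(rep(2, 200), fs = fs))
  expect_error(detect_toe_off_cop(flat, 0, 1.5),
               class = "apa_degenerate_line_error")
})

test_that("foot contact crosses 6.5 percent of body weight", {
  fs <- 100
  fz2 <- c(rep(0, 195), rep(46, 105))      # first sample above 45.5 N at 1.95 s
  x <- time_series(fz2, fs = fs)
  expect_equal(detect_foot_contact_grf(x, 700), 1.95)
  expect_equal(0.065 * 700, 45.5)
  expect_error(detect_foot_contact_grf(time_series(rep(0, 100), fs = fs), 700),
               class = "apa_no_contact_error")
})

test_that("geometric detection is invariant to rigid motion of the COP path", {
  tr <- generate_trial(trial_blueprint(seed = 31))
  rec <- tr$fp
  ev0 <- detect_all_fp(rec)
  phi <- 0.7
  Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  xy <- Rm %*% rbind(rec$cop1_ml$values, rec$cop1_ap$values) + c(3, -5)
  rec2 <- rec
  rec2$cop1_ml <- time_series(xy[1, ], fs = 800, units = "cm")
  rec2$cop1_ap <- time_series(xy[2, ], fs = 800, units = "cm")
  # rotation mixes ML/AP, so re-detect the geometry with the original onset
  path2 <- fp_cop_path(rec2)
  t_tto <- detect_trailing_toe_off(rec2$fz1, rec2$body_weight)
  toe2 <- detect_toe_off_cop(path2, ev0$apa_onset, t_tto)
  heel2 <- detect_heel_off_cop(path2, ev0$apa_onset, toe2$time)
  expect_equal(toe2$time, ev0$toe_off)
  expect_equal(heel2$time, ev0$heel_off)
  d0 <- attr(ev0, "diagnostics")
  expect_equal(toe2$d_max, d0$d1_max, tolerance = 1e-9)
  expect_equal(heel2$d_max, d0$d2_max, tolerance = 1e-9)
})

test_that("full force-plate detection keeps the event ordering on synthetic trials", {
  for (s in 1:5) {
    task <- if (s %% 2) "gait_initiation" else "step_climbing"
    tr <- generate_trial(trial_blueprint(seed = 100 + s, task = task))
    ev <- detect_all_fp(tr$fp)
    expect_true(ev$apa_onset < ev$heel_off)
    expect_true(ev$heel_off < ev$toe_off)
    expect_true(ev$toe_off < ev$foot_contact)
    expect_true(ev$toe_off < ev$trailing_toe_off)
    err <- abs(unlist(ev[c("apa_onset", "heel_off", "toe_off",
                           "foot_contact")]) -
                 unlist(tr$truth[c("apa_onset", "heel_off", "toe_off",
                                   "foot_contact")]))
    expect_lt(max(err), 0.06)
  }
})
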