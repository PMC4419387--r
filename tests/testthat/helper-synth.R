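# Shared fixtures: all test data is generated in code.

noiseless_blueprint <- function(seed, task = "gait_initiation", ...) {
  trial_blueprint(task = task, seed = seed, noise_cop = 0, noise_fz = 0,
                  noise_acc = 0, noise_gyro = 0, tilt_ap_deg = 0,
                  tilt_ml_deg = 0, ...)
}

# Brute-force oracle: per-sample point-to-line distance scan, written
# independently of the package's vectorized geometry.
oracle_max_distance <- function(path, t_start, t_end, t_line_end) {
  tt <- ts_times(path$ml)
  p0 <- c(ts_at(path$ml, t_start), ts_at(path$ap, t_start))
  p1 <- c(ts_at(path$ml, t_line_end), ts_at(path$ap, t_line_end))
  len <- sqrt(sum((p1 - p0)^2))
  best_d <- -Inf
  best_t <- NA_real_
  for (i in seq_along(tt)) {
    if (tt[i] <= t_start || tt[i] >= t_end) next
    px <- path$ml$values[i] - p0[1]
    py <- path$ap$values[i] - p0[2]
    d <- abs((p1[1] - p0[1]) * py - (p1[2] - p0[2]) * px) / len
    if (d > best_d) {
      best_d <- d
      best_t <- tt[i]
    }
  }
  list(time = best_t, d_max = best_d)
}

# Per-trial IMU summaries for a generated cohort.
summarize_imu_cohort <- function(co) {
  do.call(rbind, lapply(co$trials, function(tr) {
    prep <- apakit:::imu_preprocess(tr$imu)
    ev <- detect_all_imu(tr$imu)
    trial_summary(tr$subject, tr$task, "imu", ev, prep$acc_ml, prep$acc_ap)
  }))
}

summarize_fp_cohort <- function(co) {
  do.call(rbind, lapply(co$trials, function(tr) {
    ev <- detect_all_fp(tr$fp)
    path <- fp_cop_path(tr$fp)
    trial_summary(tr$subject, tr$task, "force_plate", ev, path$ml, path$ap)
  }))
}

# Deviations of detected events from ground truth, in seconds.
detection_errors <- function(trial, abs_fp = NULL, abs_imu = NULL) {
  fp <- detect_all_fp(trial$fp, abs_onset_threshold = abs_fp)
  imu <- detect_all_imu(trial$imu, abs_onset_threshold = abs_imu)
  truth <- trial$truth
  ev <- c("apa_onset", "heel_off", "toe_off", "foot_contact")
  c(fp = unlist(fp[ev]) - unlist(truth[ev]),
    fp.trailing = fp$trailing_toe_off - truth$trailing_toe_off,
    imu = unlist(imu[ev]) - unlist(truth[ev]))
}

# A hand-built gyro feature set for the threshold-crossing unit tests.
manual_features <- function(omega_pk, t_pk1, t_pk2 = t_pk1 + 1,
                            t_zero_cross = t_pk1 + 0.7, sign = 1) {
  structure(list(omega_pk = omega_pk, t_pk1 = t_pk1, t_pk2 = t_pk2,
                 t_zero_cross = t_zero_cross, sign = sign),
            class = "apa_gyro_features")
}
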