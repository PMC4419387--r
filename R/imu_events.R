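# Event detection from the wearable setup: trunk accelerometer (APA
# onset) and shank gyroscope (heel-off, toe-off, foot contact).
#
# The shank ML angular velocity shows a first peak (Omega_pk) around the
# step; heel-off is the first instant after APA onset at which the signal
# rises above H * Omega_pk, toe-off the first instant after the peak at
# which it drops below T * Omega_pk, and foot contact the median point
# between the zero-crossing that follows the swing and the second peak.

#' APA onset from trunk ML acceleration
#'
#' First sustained sample after the quiet window at which the
#' tilt-corrected, 3.5 Hz filtered trunk ML acceleration deviates from
#' its quiet-standing mean by more than `A` times the quiet-standing SD.
#'
#' @param trunk_acc_ml Tilt-corrected, filtered trunk ML acceleration as
#'   [time_series()] (m/s^2).
#' @param quiet_window `c(start, end)` seconds of quiet standing.
#' @param A Threshold multiplier on the quiet-standing SD.
#' @param sustain_s Minimum hold time of the excursion (default two
#'   samples at 50 Hz).
#' @param abs_threshold Absolute threshold in m/s^2 for noiseless signals.
#' @param refine Smooth-step intercept refinement of the crossing (see
#'   [detect_onset_cop()]).
#' @param refine_window_s,confirm_mult See [detect_onset_cop()].
#' @param interp Linearly interpolate the crossing between the
#'   bracketing samples instead of returning the sample time.
#' @export
detect_onset_imu <- function(trunk_acc_ml, quiet_window, A = 2,
                             sustain_s = 0.04, abs_threshold = NULL,
                             refine = FALSE, refine_window_s = 0.25,
                             confirm_mult = 5, interp = FALSE) {
  detect_onset_core(trunk_acc_ml, quiet_window, A, sustain_s,
                    abs_threshold = abs_threshold, refine = refine,
                    refine_window_s = refine_window_s,
                    confirm_mult = confirm_mult, interp = interp,
                    what = "trunk ML acceleration")
}

# Local maxima of v with height and topographic prominence >= min_prom
# (the height floor rejects filter-ringing lobes that straddle zero and
# would otherwise gain prominence from their negative dips).
find_peaks <- function(v, min_prom) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  cand <- cand[v[cand] >= min_prom]
  keep <- vapply(cand, function(i) {
    # walk left and right to the nearest higher ground; prominence is the
    # peak height above the higher of the two intervening minima
    left <- v[seq_len(i - 1L)]
    right <- v[seq(i + 1L, n)]
    hl <- which(left >= v[i])
    lmin <- if (length(hl)) min(left[seq(max(hl), i - 1L)]) else min(left)
    hr <- which(right >= v[i])
    rmin <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    (v[i] - max(lmin, rmin)) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Shank angular-velocity landmarks
#'
#' Finds the first and second qualifying peaks of the filtered shank ML
#' angular velocity after APA onset (local maxima with prominence of at
#' least `prominence_frac` of the post-onset maximum), the value of the
#' first peak (Omega_pk), and the last zero-crossing preceding the second
#' peak (linearly interpolated between the bracketing samples).  If the
#' first qualifying extremum after onset is negative the signal is taken
#' as mirror-mounted and negated (`sign = -1`).
#'
#' @param shank_gyro_ml Filtered shank ML angular velocity as
#'   [time_series()] (deg/s).
#' @param t_onset APA onset time (s); the search starts there.
#' @param prominence_frac Peak-qualification prominence, as a fraction of
#'   the post-onset absolute maximum.
#' @return An object of class `apa_gyro_features`: `omega_pk`, `t_pk1`,
#'   `t_pk2`, `t_zero_cross`, `sign`.
#' @export
extract_gyro_features <- function(shank_gyro_ml, t_onset,
                                  prominence_frac = 0.10) {
  tt <- ts_times(shank_gyro_ml)
  idx <- which(tt > t_onset)
  if (length(idx) < 5L) {
    apa_error("apa_missing_peak_error", "too few samples after APA onset")
  }
  v <- shank_gyro_ml$values[idx]
  prom <- prominence_frac * max(abs(v))
  pk_pos <- find_peaks(v, prom)
  pk_neg <- find_peaks(-v, prom)
  sgn <- 1
  first_pos <- if (length(pk_pos)) pk_pos[1] else Inf
  first_neg <- if (length(pk_neg)) pk_neg[1] else Inf
  if (first_neg < first_pos) {
    sgn <- -1
    v <- -v
    pk_pos <- pk_neg
  }
  if (length(pk_pos) < 2L) {
    apa_error("apa_missing_peak_error",
              sprintf("found %d qualifying angular-velocity peak(s); need 2",
                      length(pk_pos)))
  }
  i1 <- pk_pos[1]
  i2 <- pk_pos[2]
  # last zero-crossing strictly before the second peak
  seg <- v[i1:i2]
  flips <- which(seg[-length(seg)] * seg[-1] <= 0 & seg[-length(seg)] != seg[-1])
  if (!length(flips)) {
    apa_error("apa_missing_crossing_error",
              "no zero-crossing between the two angular-velocity peaks")
  }
  j <- i1 + flips[length(flips)] - 1L
  t_all <- tt[idx]
  f <- v[j] / (v[j] - v[j + 1L])
  t_zc <- t_all[j] + f * (t_all[j + 1L] - t_all[j])
  structure(list(omega_pk = v[i1], t_pk1 = t_all[i1], t_pk2 = t_all[i2],
                 t_zero_cross = t_zc, sign = sgn),
            class = "apa_gyro_features")
}

#' @export
print.apa_gyro_features <- function(x, ...) {
  cat(sprintf(
    "<gyro features> Omega_pk %.1f deg/s at %.3f s; zero-cross %.3f s; 2nd peak %.3f s%s\n",
    x$omega_pk, x$t_pk1, x$t_zero_cross, x$t_pk2,
    if (x$sign < 0) " (sign-normalized)" else ""))
  invisible(x)
}

gyro_oriented <- function(shank_gyro_ml, features) {
  v <- shank_gyro_ml$values * features$sign
  list(v = v, tt = ts_times(shank_gyro_ml))
}

#' Heel-off from shank angular velocity
#'
#' First instant in `(t_onset, t_pk1]` at which the (sign-normalized)
#' angular velocity rises above `H * Omega_pk`.  With `interp = TRUE`
#' (default) the crossing is linearly interpolated between the bracketing
#' samples; with `interp = FALSE` the first exceeding sample time is
#' returned.
#'
#' @param shank_gyro_ml Filtered shank ML angular velocity.
#' @param t_onset APA onset (s).
#' @param features [extract_gyro_features()] output.
#' @param H Heel-off fraction of Omega_pk.
#' @param interp Sub-sample interpolation of the crossing.
#' @export
detect_heel_off_imu <- function(shank_gyro_ml, t_onset, features, H,
                                interp = TRUE) {
  g <- gyro_oriented(shank_gyro_ml, features)
  thr <- H * features$omega_pk
  idx <- which(g$tt > t_onset & g$tt <= features$t_pk1)
  if (!length(idx)) {
    apa_error("apa_detection_error", "no samples between onset and the first peak")
  }
  k <- which(g$v[idx] > thr)[1]
  if (is.na(k)) {
    apa_error("apa_detection_error",
              sprintf("angular velocity never exceeds H * Omega_pk = %.2f deg/s before the peak", thr))
  }
  i <- idx[k]
  if (interp && i > idx[1]) interp_crossing(g$v, g$tt, i, thr) else g$tt[i]
}

#' Toe-off from shank angular velocity
#'
#' First instant after the first peak at which the angular velocity drops
#' below `T * Omega_pk`.
#'
#' @inheritParams detect_heel_off_imu
#' @param T_ Toe-off fraction of Omega_pk.
#' @export
detect_toe_off_imu <- function(shank_gyro_ml, features, T_, interp = TRUE) {
  g <- gyro_oriented(shank_gyro_ml, features)
  thr <- T_ * features$omega_pk
  idx <- which(g$tt > features$t_pk1)
  if (!length(idx)) {
    apa_error("apa_detection_error", "record ends at the first peak")
  }
  k <- which(g$v[idx] < thr)[1]
  if (is.na(k)) {
    apa_error("apa_detection_error",
              sprintf("angular velocity never drops below T * Omega_pk = %.2f deg/s", thr))
  }
  i <- idx[k]
  if (!interp || i == 1L) return(g$tt[i])
  # downward crossing between i-1 and i
  v0 <- g$v[i - 1L]
  v1 <- g$v[i]
  if (v0 <= thr || v1 >= v0) return(g$tt[i])
  f <- (v0 - thr) / (v0 - v1)
  if (!is.finite(f) || f < 0 || f > 1) return(g$tt[i])
  max(g$tt[i - 1L] + f * (g$tt[i] - g$tt[i - 1L]), features$t_pk1)
}

#' Foot contact from shank angular velocity
#'
#' Median point between the zero-crossing following the swing and the
#' second angular-velocity peak.
#'
#' @param features [extract_gyro_features()] output.
#' @return Contact time (s); if the zero-crossing and the peak coincide
#'   the result carries a `degenerate` attribute.
#' @export
detect_foot_contact_imu <- function(features) {
  t <- (features$t_zero_cross + features$t_pk2) / 2
  if (features$t_zero_cross >= features$t_pk2 - 1e-12) {
    attr(t, "degenerate") <- TRUE
  }
  t
}

#' Full inertial event detection for one trial
#'
#' Tilt-corrects the trunk accelerations, removes the quiet-standing mean
#' from the shank gyroscope, filters both at 3.5 Hz (zero-phase), then
#' runs the four detectors with the given thresholds.
#'
#' @param rec An `apa_imu_recording`.
#' @param thr An `apa_thresholds` set; defaults to the calibrated factors
#'   for the recording's task ([default_thresholds()]).
#' @param cutoff Filter cutoff in Hz (default 3.5).
#' @param refine_onset Quadratic-vertex onset refinement (default `TRUE`).
#' @param interp Sub-sample interpolation of gyro threshold crossings.
#' @param abs_onset_threshold Absolute onset threshold (m/s^2) for
#'   noiseless recordings.
#' @return An `apa_events` object (`source = "imu"`, no trailing
#'   toe-off), with a `diagnostics` attribute (Omega_pk, peak times,
#'   onset threshold).
#' @export
detect_all_imu <- function(rec, thr = default_thresholds(rec$task),
                           cutoff = 3.5, refine_onset = TRUE, interp = TRUE,
                           abs_onset_threshold = NULL) {
  prep <- imu_preprocess(rec, cutoff)
  onset <- detect_onset_imu(prep$acc_ml, rec$quiet_window, A = thr$A,
                            refine = FALSE,
                            abs_threshold = abs_onset_threshold)
  if (refine_onset) {
    # the 3.5 Hz detection band smears the onset by several samples at
    # 50 Hz; localize the crossing on a wider band of the same signal
    t_ref <- refine_onset_on(prep$acc_ml_wide, rec$quiet_window,
                             attr(onset, "t_cross"), max_back_s = 0.25)
    attrs <- attributes(onset)
    onset <- t_ref
    attributes(onset) <- attrs
  }
  feats <- extract_gyro_features(prep$gyro, as.numeric(onset))
  t_ho <- detect_heel_off_imu(prep$gyro, as.numeric(onset), feats, thr$H,
                              interp = interp)
  t_to <- detect_toe_off_imu(prep$gyro, feats, thr$T, interp = interp)
  t_fc <- detect_foot_contact_imu(feats)
  ev <- gait_events(apa_onset = as.numeric(onset), heel_off = t_ho,
                    toe_off = t_to, foot_contact = as.numeric(t_fc),
                    source = "imu")
  attr(ev, "diagnostics") <- list(
    omega_pk = feats$omega_pk, t_pk1 = feats$t_pk1, t_pk2 = feats$t_pk2,
    t_zero_cross = feats$t_zero_cross, gyro_sign = feats$sign,
    onset_threshold = attr(onset, "threshold"),
    onset_crossing = attr(onset, "t_cross"))
  apa_log("IMU events: onset %.3f heel %.3f toe %.3f contact %.3f (Omega_pk %.1f deg/s)",
          ev$apa_onset, ev$heel_off, ev$toe_off, ev$foot_contact, feats$omega_pk)
  ev
}

# Tilt-correct and filter the channels needed for detection; shared by
# detect_all_imu() and calibrate() (which pre-filters once per trial).
imu_preprocess <- function(rec, cutoff = 3.5) {
  corr <- tilt_correct(rec$trunk_acc_v, rec$trunk_acc_ml, rec$trunk_acc_ap,
                       rec$quiet_window)
  spec <- filter_spec(cutoff)
  gyro <- rec$shank_gyro_ml
  qidx <- ts_window_idx(gyro, rec$quiet_window[1], rec$quiet_window[2])
  gyro <- time_series(gyro$values - mean(gyro$values[qidx]), fs = gyro$fs,
                      t0 = gyro$t0, units = gyro$units)
  wide <- filter_spec(min(10, 0.4 * rec$trunk_acc_ml$fs))
  list(acc_ml = zero_phase_lowpass(corr$trunk_acc_ml, spec),
       acc_ap = zero_phase_lowpass(corr$trunk_acc_ap, spec),
       acc_v = zero_phase_lowpass(corr$trunk_acc_v, spec),
       acc_ml_wide = zero_phase_lowpass(corr$trunk_acc_ml, wide),
       gyro = zero_phase_lowpass(gyro, spec),
       angles = corr$angles)
}
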