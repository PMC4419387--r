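# Synthetic paired force-plate + IMU trials with known ground-truth
# events.
#
# Signal construction is chosen so that the programmed event times
# coincide with the landmarks the detectors look for:
#
# * the COP path is built from raised-cosine (smooth-step) segments whose
#   vertices (zero-velocity points) sit exactly at APA onset, heel-off,
#   toe-off and trailing toe-off; since each segment traverses a straight
#   chord, the maximal point-to-line distances d1_max / d2_max land
#   exactly on the programmed toe-off / heel-off;
# * plate forces are complementary raised-cosine load transfers solved so
#   that fz2 crosses the 6.5 %-body-weight contact threshold exactly at
#   foot contact and fz1 decays through it exactly at trailing toe-off;
# * the shank angular-velocity pulse flanks are placed so that the
#   crossings of H_true * Omega_pk and T_true * Omega_pk occur exactly at
#   heel-off and toe-off, and the post-swing zero-crossing / second peak
#   straddle foot contact symmetrically;
# * trunk ML acceleration is a single-gain image of the ML COP (the
#   mono-segmental coupling hypothesis made literal), while the AP
#   channel mixes a COP-driven part with an independent multi-segmental
#   component; the triplet is rotated by a programmed sensor tilt and
#   gravity is added.
#
# All segment transitions are smooth and slow relative to the detection
# filters' cutoffs, so zero-phase filtering leaves the landmarks in place.

rcstep <- function(t, t0, t1) {
  if (t1 <= t0) return(as.numeric(t >= t1))
  u <- (t - t0) / (t1 - t0)
  u <- pmin(pmax(u, 0), 1)
  (1 - cos(pi * u)) / 2
}

blueprint_error <- function(msg, ...) {
  apa_error("apa_blueprint_error", sprintf(msg, ...))
}

#' Blueprint of one synthetic trial
#'
#' Defaults emulate a healthy-adult trial: a 10 s quiet-standing lead-in
#' followed by imbalance, unloading and swing phases with the COP
#' excursions, phase durations and trunk-acceleration coupling reported
#' for gait initiation and step climbing (COP imbalance ML ~2.2 / 2.5 cm,
#' unloading ML ~ -9.4 cm, trunk gain ~0.088 (m/s^2)/cm).  The
#' `pd_like` mode scales the ML imbalance excursion by 0.4 and the ML
#' unloading by 0.8 (hypometric APAs) and removes task scaling.
#'
#' @param task `"gait_initiation"` or `"step_climbing"`.
#' @param quiet_s Quiet-standing lead-in (s); movement starts at its end.
#' @param dur_imbalance,dur_unloading,dur_swing Phase durations (s).
#' @param dur_double_support Foot contact to trailing toe-off (s).
#' @param imb_ml,imb_ap,unl_ml,unl_ap COP excursions (cm): imbalance ML
#'   positive toward the stepping side, imbalance AP negative (backward),
#'   unloading ML negative (toward the stance side).
#' @param swing_ml,swing_ap Additional COP excursion from toe-off to
#'   trailing toe-off (cm).
#' @param k_ml,k_ap Trunk-acceleration / COP coupling gains ((m/s^2)/cm).
#' @param ap_extra_sd SD of the independent (multi-segmental) trunk AP
#'   component's amplitude (m/s^2).
#' @param acc_v_amp Vertical trunk-acceleration excursion (m/s^2).
#' @param omega_pk First shank angular-velocity peak (deg/s).
#' @param omega2_frac,neg_frac Second-peak and inter-peak dip amplitudes
#'   as fractions of `omega_pk`.
#' @param fc_half_gap Half-gap between the zero-crossing and the second
#'   peak, centred on foot contact (s).
#' @param thresholds_true `apa_thresholds` at which the inertial
#'   crossings are aligned with the ground-truth events (defaults to the
#'   task's calibrated factors).
#' @param onset_step_acc Small smooth step added to trunk ML acceleration
#'   centred on the onset (m/s^2); 0 = none.
#' @param onset_marker_A If non-`NULL`, size the onset step automatically
#'   as twice `onset_marker_A` times the trial's realized filtered quiet
#'   noise SD, so that the crossing of `A_true * SD` sits exactly at the
#'   true onset (used by calibration cohorts).
#' @param noise_cop,noise_fz,noise_acc,noise_gyro Channel noise SDs
#'   (cm, N, m/s^2, deg/s); set to 0 for noiseless trials.
#' @param tilt_ap_deg,tilt_ml_deg Programmed static sensor tilt (deg).
#' @param body_weight Body weight (N).
#' @param fz2_final_frac Fraction of body weight on plate 2 after
#'   contact.
#' @param w_contact,w_lift Load-transfer rise/decay times (s).
#' @param post_s Recording tail after trailing toe-off (s).
#' @param fs_fp,fs_imu Sampling rates (Hz).
#' @param seed RNG seed for the noise.
#' @return An object of class `apa_blueprint`.
#' @export
trial_blueprint <- function(task = c("gait_initiation", "step_climbing"),
                            quiet_s = 10,
                            dur_imbalance = NULL, dur_unloading = 0.30,
                            dur_swing = NULL, dur_double_support = 0.25,
                            imb_ml = NULL, imb_ap = NULL,
                            unl_ml = NULL, unl_ap = 1.0,
                            swing_ml = -0.8, swing_ap = 12,
                            k_ml = 0.088, k_ap = 0.04, ap_extra_sd = 0.12,
                            acc_v_amp = 0.08,
                            omega_pk = 150, omega2_frac = 0.6, neg_frac = 0.3,
                            fc_half_gap = 0.12,
                            thresholds_true = NULL, onset_step_acc = 0,
                            onset_marker_A = NULL,
                            noise_cop = 0.01, noise_fz = 2,
                            noise_acc = 0.005, noise_gyro = 0.5,
                            tilt_ap_deg = 5, tilt_ml_deg = 2,
                            body_weight = 700, fz2_final_frac = 0.55,
                            w_contact = 0.25, w_lift = 0.30, post_s = 1.0,
                            fs_fp = 800, fs_imu = 50, seed = 1,
                            pd_like = FALSE) {
  task <- match.arg(task)
  gait <- task == "gait_initiation"
  dur_imbalance <- dur_imbalance %||% if (gait) 0.40 else 0.47
  dur_swing <- dur_swing %||% if (gait) 0.50 else 0.65
  imb_ml <- imb_ml %||% if (gait) 2.17 else 2.48
  imb_ap <- imb_ap %||% if (gait) -2.0 else -1.8
  unl_ml <- unl_ml %||% if (gait) -9.35 else -9.55
  thresholds_true <- thresholds_true %||% default_thresholds(task)
  if (pd_like) {
    imb_ml <- 0.4 * imb_ml
    unl_ml <- 0.8 * unl_ml
  }
  bp <- list(task = task, quiet_s = quiet_s, dur_imbalance = dur_imbalance,
             dur_unloading = dur_unloading, dur_swing = dur_swing,
             dur_double_support = dur_double_support,
             imb_ml = imb_ml, imb_ap = imb_ap, unl_ml = unl_ml,
             unl_ap = unl_ap, swing_ml = swing_ml, swing_ap = swing_ap,
             k_ml = k_ml, k_ap = k_ap, ap_extra_sd = ap_extra_sd,
             acc_v_amp = acc_v_amp, omega_pk = omega_pk,
             omega2_frac = omega2_frac, neg_frac = neg_frac,
             fc_half_gap = fc_half_gap,
             thresholds_true = thresholds_true,
             onset_step_acc = onset_step_acc,
             onset_marker_A = onset_marker_A,
             noise_cop = noise_cop, noise_fz = noise_fz,
             noise_acc = noise_acc, noise_gyro = noise_gyro,
             tilt_ap_deg = tilt_ap_deg, tilt_ml_deg = tilt_ml_deg,
             body_weight = body_weight, fz2_final_frac = fz2_final_frac,
             w_contact = w_contact, w_lift = w_lift, post_s = post_s,
             fs_fp = fs_fp, fs_imu = fs_imu, seed = seed,
             pd_like = pd_like)
  class(bp) <- "apa_blueprint"
  validate_blueprint(bp)
  bp
}

blueprint_times <- function(bp) {
  t_on <- bp$quiet_s
  t_ho <- t_on + bp$dur_imbalance
  t_to <- t_ho + bp$dur_unloading
  t_fc <- t_to + bp$dur_swing
  t_tto <- t_fc + bp$dur_double_support
  list(t_on = t_on, t_ho = t_ho, t_to = t_to, t_fc = t_fc, t_tto = t_tto,
       t_end = t_tto + bp$post_s)
}

# Gyro pulse placement: solve the flank timings so that the crossings of
# H_true * Omega_pk (rising) and T_true * Omega_pk (falling) land exactly
# on heel-off and toe-off.  When T_true is ~1 the toe-off crossing sits
# at the peak itself, so the peak is placed at toe-off.
gyro_timing <- function(bp, tm) {
  H <- bp$thresholds_true$H
  T_ <- bp$thresholds_true$T
  aH <- acos(1 - 2 * min(max(H, 0), 1))
  aT <- acos(2 * min(max(T_, 0), 1) - 1)
  if (aT < 0.2) {
    t_pk1 <- tm$t_to
    w_r <- (tm$t_to - tm$t_ho) * pi / (pi - aH)
    t_r <- t_pk1 - w_r
    w_f <- min(0.25, max(0.10, tm$t_fc - t_pk1 - 0.17))
  } else {
    # choose the fall width within the room left by the toe-off crossing
    # (T * Omega_pk at t_to), the heel-off flank and the second-peak
    # train before foot contact; then the rise width follows from the
    # heel-off crossing (H * Omega_pk at t_ho) meeting the peak
    w_f_max1 <- (tm$t_fc - 0.17 - tm$t_to) / max(1 - aT / pi, 0.05)
    # reserve >= 0.10 s of rise between heel-off and the peak; shorter
    # rises do not survive the 3.5 Hz detection filter at 50 Hz
    w_f_max2 <- (tm$t_to - tm$t_ho - 0.10) * pi / aT
    w_f <- min(0.30, w_f_max1, w_f_max2)
    if (w_f < 0.05) {
      blueprint_error("unloading phase (%.2f s) incompatible with the gyro pulse (fall time %.3f s)",
                      bp$dur_unloading, w_f)
    }
    t_pk1 <- tm$t_to - (aT / pi) * w_f
    w_r <- min((t_pk1 - tm$t_ho) / max(1 - aH / pi, 0.1),
               t_pk1 - tm$t_on - 0.05)
    t_r <- t_pk1 - w_r
  }
  if (t_r <= tm$t_on) {
    blueprint_error("gyro pulse would start before APA onset (t_r = %.3f s)", t_r)
  }
  if (w_f < 0.03 || w_f > 1.5) {
    blueprint_error("unloading phase (%.2f s) incompatible with the gyro pulse (fall time %.3f s)",
                    bp$dur_unloading, w_f)
  }
  t_f_end <- t_pk1 + w_f
  # shrink the contact half-gap when the swing is short, keeping the
  # zero-crossing / second-peak pair symmetric about foot contact and
  # leaving at least 0.12 s for the inter-peak negative lobe (shorter
  # lobes are smoothed above zero by the 3.5 Hz filter at 50 Hz)
  d <- min(bp$fc_half_gap, tm$t_fc - t_f_end - 0.12)
  if (d < 0.04) {
    blueprint_error("swing phase too short for the gyro pulse train (gap %.3f s)",
                    tm$t_fc - t_f_end)
  }
  t_zc <- tm$t_fc - d
  t_pk2 <- tm$t_fc + d
  list(t_r = t_r, w_r = w_r, t_pk1 = t_pk1, w_f = w_f, t_f_end = t_f_end,
       t_zc = t_zc, t_pk2 = t_pk2, w_2f = 0.20)
}

validate_blueprint <- function(bp) {
  durs <- c(bp$dur_imbalance, bp$dur_unloading, bp$dur_swing,
            bp$dur_double_support)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    blueprint_error("all phase durations must be > 0")
  }
  if (bp$fs_fp < bp$fs_imu) blueprint_error("fs_fp must be >= fs_imu")
  if (bp$imb_ml <= 0) blueprint_error("imbalance ML excursion must be positive (toward the stepping side)")
  if (bp$unl_ml >= 0) blueprint_error("unloading ML excursion must be negative (toward the stance side)")
  if (bp$quiet_s < 3) blueprint_error("quiet lead-in must be at least 3 s")
  tm <- blueprint_times(bp)
  gyro_timing(bp, tm)
  # COP geometry: the programmed toe-off must dominate the d1 criterion
  p_ho <- c(bp$imb_ml, bp$imb_ap)
  p_to <- p_ho + c(bp$unl_ml, bp$unl_ap)
  p_tto <- p_to + c(bp$swing_ml, bp$swing_ap)
  d <- function(p, q) abs(q[1] * p[2] - q[2] * p[1]) / sqrt(sum(q^2))
  if (sum(p_tto^2) == 0 || d(p_to, p_tto) <= d(p_ho, p_tto)) {
    blueprint_error("COP geometry: toe-off point does not dominate the distance from line L1")
  }
  if (sum(p_to^2) == 0 || d(p_ho, p_to) <= 0) {
    blueprint_error("COP geometry: heel-off point is collinear with line L2")
  }
  # load-transfer timing: fz1 must cross the floor after transfer completes
  thr <- 0.065
  t_cs <- tm$t_fc - (bp$w_contact / pi) *
    acos(1 - 2 * thr / bp$fz2_final_frac)
  if (t_cs <= tm$t_to) blueprint_error("contact transfer would start before toe-off")
  if (tm$t_tto < t_cs + bp$w_contact) {
    blueprint_error("double support too short for the programmed load transfer")
  }
  invisible(bp)
}

# Continuous-time shank angular velocity for given pulse timings.
gyro_fn <- function(bp, gt) {
  Om <- bp$omega_pk
  function(t) {
    Om * rcstep(t, gt$t_r, gt$t_pk1) -
      Om * rcstep(t, gt$t_pk1, gt$t_pk1 + gt$w_f) -
      bp$neg_frac * Om * (1 - cos(2 * pi * pmin(pmax(
        (t - gt$t_f_end) / (gt$t_zc - gt$t_f_end), 0), 1))) / 2 +
      bp$omega2_frac * Om * (rcstep(t, gt$t_zc, gt$t_pk2) -
                               rcstep(t, gt$t_pk2, gt$t_pk2 + gt$w_2f))
  }
}

# The 3.5 Hz detection filter is not transparent to the gyro pulse (its
# flanks carry content near and above the cutoff), so analytic flank
# placement leaves the filtered threshold crossings 10-20 ms off the
# programmed events.  This fixed-point iteration nudges the rise
# placement and fall width until the detectors, run on the filtered
# clean pulse, recover heel-off and toe-off at the programmed times.
align_gyro <- function(bp, tm, gt, cutoff = 3.5, n_iter = 8, tol = 1e-3) {
  H <- bp$thresholds_true$H
  T_ <- bp$thresholds_true$T
  aH <- acos(1 - 2 * min(max(H, 0), 1))
  aT <- acos(2 * min(max(T_, 0), 1) - 1)
  peak_branch <- aT < 0.2
  tt <- seq(0, tm$t_end, by = 1 / bp$fs_imu)
  errs_of <- function(gt) {
    filt <- zero_phase_lowpass(
      time_series(gyro_fn(bp, gt)(tt), fs = bp$fs_imu, units = "deg/s"),
      filter_spec(cutoff))
    tryCatch({
      feats <- extract_gyro_features(filt, tm$t_on)
      if (feats$omega_pk < 0.4 * bp$omega_pk) return(NULL)
      c(detect_heel_off_imu(filt, tm$t_on, feats, H) - tm$t_ho,
        detect_toe_off_imu(filt, feats, T_) - tm$t_to)
    }, apa_error = function(e) NULL)
  }
  best <- gt
  best_err <- Inf
  cur <- gt
  for (it in seq_len(n_iter)) {
    e <- errs_of(cur)
    if (is.null(e)) break
    if (max(abs(e)) < best_err) {
      best <- cur
      best_err <- max(abs(e))
    }
    if (best_err < tol) break
    # damped updates: near the filter's attenuation edge the response of
    # the crossings to the flank widths is strongly nonlinear
    if (peak_branch) {
      d_wr <- 0.6 * (e[1] - e[2]) / (1 - aH / pi)
      cur$w_r <- max(cur$w_r + d_wr, 0.10)
      cur$t_r <- cur$t_r - 0.8 * e[2] - d_wr
    } else {
      cur$t_r <- cur$t_r - 0.8 * e[1]
      cur$w_f <- min(max(cur$w_f + 0.5 * pi * (e[1] - e[2]) / aT, 0.12), 1.5)
    }
    cur$t_r <- max(cur$t_r, tm$t_on + 0.02)
    cur$t_pk1 <- cur$t_r + cur$w_r
    cur$t_f_end <- cur$t_pk1 + cur$w_f
    if (cur$t_f_end > cur$t_zc - 0.10) {
      cur$w_f <- max(cur$t_zc - 0.10 - cur$t_pk1, 0.10)
      cur$t_f_end <- cur$t_pk1 + cur$w_f
    }
  }
  best
}

# The 10 Hz COP filter slightly overshoots the decelerating path ends
# (Butterworth step-response ringing), so the filtered path's maximal
# point-to-line distances land a few ms past the programmed vertices.
# As with the gyro pulse, the segment boundaries are nudged until the
# geometric detectors, run on the filtered clean path, recover heel-off
# and toe-off at the programmed times.
align_cop <- function(bp, tm, n_iter = 3, tol = 5e-4, cutoff = 10) {
  cb <- list(b_ho = tm$t_ho, b_to = tm$t_to)
  tt <- seq(0, tm$t_end, by = 1 / bp$fs_fp)
  spec <- filter_spec(cutoff)
  for (it in seq_len(n_iter)) {
    bp$cop_bounds <- cb
    sig <- blueprint_signals(bp, 0, gt = gyro_timing(bp, tm))
    path <- cop_path(
      zero_phase_lowpass(time_series(sig$cop_ml(tt), fs = bp$fs_fp), spec),
      zero_phase_lowpass(time_series(sig$cop_ap(tt), fs = bp$fs_fp), spec))
    res <- tryCatch({
      toe <- detect_toe_off_cop(path, tm$t_on, tm$t_tto)
      heel <- detect_heel_off_cop(path, tm$t_on, toe$time)
      c(heel$time - tm$t_ho, toe$time - tm$t_to)
    }, apa_error = function(e) NULL)
    if (is.null(res)) break
    if (all(abs(res) < tol)) break
    cb$b_ho <- min(max(cb$b_ho - res[1], tm$t_on + 0.6 * bp$dur_imbalance),
                   tm$t_ho + 0.4 * bp$dur_unloading)
    cb$b_to <- min(max(cb$b_to - res[2], cb$b_ho + 0.5 * bp$dur_unloading),
                   tm$t_to + 0.4 * bp$dur_swing)
  }
  cb
}

# Continuous-time clean signal functions for a blueprint (no noise, no
# tilt); shared by the force-plate and IMU channel builders.
blueprint_signals <- function(bp, ap_extra_amp = 0, gt = NULL) {
  tm <- blueprint_times(bp)
  gt <- gt %||% gyro_timing(bp, tm)
  cb <- bp$cop_bounds %||% list(b_ho = tm$t_ho, b_to = tm$t_to)
  cop_ml <- function(t) {
    bp$imb_ml * rcstep(t, tm$t_on, cb$b_ho) +
      bp$unl_ml * rcstep(t, cb$b_ho, cb$b_to) +
      bp$swing_ml * rcstep(t, cb$b_to, tm$t_tto)
  }
  cop_ap <- function(t) {
    bp$imb_ap * rcstep(t, tm$t_on, cb$b_ho) +
      bp$unl_ap * rcstep(t, cb$b_ho, cb$b_to) +
      bp$swing_ap * rcstep(t, cb$b_to, tm$t_tto)
  }
  BW <- bp$body_weight
  f_final <- bp$fz2_final_frac * BW
  thr <- 0.065 * BW
  t_cs <- tm$t_fc - (bp$w_contact / pi) * acos(1 - 2 * thr / f_final)
  fz2 <- function(t) f_final * rcstep(t, t_cs, t_cs + bp$w_contact)
  lift_total <- BW - f_final
  lam <- 1 - thr / lift_total
  t_a <- tm$t_tto - (bp$w_lift / pi) * acos(1 - 2 * lam)
  fz1 <- function(t) {
    pmax(BW - fz2(t) - lift_total * rcstep(t, t_a, t_a + bp$w_lift), 0)
  }
  gyro <- gyro_fn(bp, gt)
  # the onset marker is a smooth step centred on the onset, so its
  # half-height crossing sits at the onset by symmetry even after
  # zero-phase filtering (a sharp step would ring); the centre can be
  # nudged by the marker alignment iteration
  w_m <- 0.12
  m_c <- bp$marker_center %||% tm$t_on
  acc_ml <- function(t) {
    bp$k_ml * cop_ml(t) +
      bp$onset_step_acc * rcstep(t, m_c - w_m / 2, m_c + w_m / 2)
  }
  acc_ap <- function(t) {
    bp$k_ap * cop_ap(t) +
      ap_extra_amp * (rcstep(t, tm$t_on, tm$t_ho + 0.1) -
                        rcstep(t, tm$t_ho + 0.1, tm$t_to + 0.2))
  }
  acc_v <- function(t) {
    bp$acc_v_amp * (rcstep(t, tm$t_ho, tm$t_to) - rcstep(t, tm$t_to, tm$t_fc))
  }
  list(tm = tm, gt = gt, cop_ml = cop_ml, cop_ap = cop_ap, fz1 = fz1,
       fz2 = fz2, gyro = gyro, acc_ml = acc_ml, acc_ap = acc_ap,
       acc_v = acc_v)
}

#' Generate one synthetic paired trial
#'
#' Evaluates the blueprint's continuous-time signal model on the
#' force-plate and IMU sampling grids, applies the programmed sensor
#' tilt and gravity to the trunk accelerations, adds Gaussian channel
#' noise, and rounds all samples to 9 significant digits (so that
#' generation is deterministic across platforms after a CSV round trip).
#'
#' @param bp A [trial_blueprint()].
#' @return `list(fp, imu, truth, blueprint)`: a `apa_fp_recording`, a
#'   `apa_imu_recording`, and the ground-truth `apa_events`.
#' @export
generate_trial <- function(bp) {
  if (!inherits(bp, "apa_blueprint")) {
    apa_error("apa_schema_error", "bp must be a trial_blueprint")
  }
  validate_blueprint(bp)
  with_seed(bp$seed, {
    ap_extra_amp <- stats::rnorm(1, 0, bp$ap_extra_sd)
    tm0 <- blueprint_times(bp)
    gt <- align_gyro(bp, tm0, gyro_timing(bp, tm0))
    bp$cop_bounds <- align_cop(bp, tm0)
    sig <- blueprint_signals(bp, ap_extra_amp, gt = gt)
    tm <- sig$tm
    qw <- c(0, bp$quiet_s - 2)
    n_fp <- as.integer(round(tm$t_end * bp$fs_fp)) + 1L
    n_imu <- as.integer(round(tm$t_end * bp$fs_imu)) + 1L
    t_fp <- (seq_len(n_fp) - 1) / bp$fs_fp
    t_imu <- (seq_len(n_imu) - 1) / bp$fs_imu
    nz <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    q9 <- function(x) signif(x, 9)

    mk_fp <- function(v, units) time_series(q9(v), fs = bp$fs_fp, t0 = 0,
                                            units = units)
    fp <- force_plate_recording(
      cop1_ml = mk_fp(sig$cop_ml(t_fp) + nz(n_fp, bp$noise_cop), "cm"),
      cop1_ap = mk_fp(sig$cop_ap(t_fp) + nz(n_fp, bp$noise_cop), "cm"),
      fz1 = mk_fp(sig$fz1(t_fp) + nz(n_fp, bp$noise_fz), "N"),
      fz2 = mk_fp(sig$fz2(t_fp) + nz(n_fp, bp$noise_fz), "N"),
      body_weight = bp$body_weight, quiet_window = qw, task = bp$task)

    theta <- bp$tilt_ap_deg * pi / 180
    phi <- bp$tilt_ml_deg * pi / 180
    R <- tilt_rotation(theta, phi)
    acc_noise <- rbind(nz(n_imu, bp$noise_acc), nz(n_imu, bp$noise_acc),
                       nz(n_imu, bp$noise_acc))
    if (!is.null(bp$onset_marker_A) && bp$noise_acc > 0) {
      # size the onset marker from this trial's realized filtered quiet
      # noise, matching the SD the detector will estimate, then nudge
      # its centre until the crossing of A_true * SD on the clean
      # filtered signal sits exactly at the true onset (the imbalance
      # rise contributes to the flank and would otherwise bias it)
      eff <- (R %*% acc_noise)[2, ]
      filt <- zero_phase_lowpass(time_series(eff, fs = bp$fs_imu),
                                 filter_spec(3.5))
      qidx <- ts_window_idx(filt, 0, bp$quiet_s - 2)
      sd_hat <- stats::sd(filt$values[qidx])
      bp$onset_step_acc <- 2 * bp$onset_marker_A * sd_hat
      bp$marker_center <- tm$t_on
      # align the realized (noise-included) first sustained crossing of
      # A_true * SD with the true onset; noise makes the first passage
      # systematically earlier than the clean crossing, so alignment on
      # the clean flank alone would leave a bias of one grid step
      for (it in 1:4) {
        sig <- blueprint_signals(bp, ap_extra_amp, gt = gt)
        noisy <- time_series(sig$acc_ml(t_imu) + eff, fs = bp$fs_imu)
        nfilt <- zero_phase_lowpass(noisy, filter_spec(3.5))
        e <- tryCatch({
          on <- detect_onset_core(nfilt, qw, bp$onset_marker_A, 0.04,
                                  interp = TRUE)
          attr(on, "t_cross") - tm$t_on
        }, apa_error = function(err) NA_real_)
        if (!is.finite(e) || abs(e) < 2e-3) break
        bp$marker_center <- min(max(bp$marker_center - e,
                                    tm$t_on - 0.15), tm$t_on + 0.15)
      }
      sig <- blueprint_signals(bp, ap_extra_amp, gt = gt)
    }
    world <- rbind(GRAVITY + sig$acc_v(t_imu), sig$acc_ml(t_imu),
                   sig$acc_ap(t_imu))
    sensor <- t(R) %*% world + acc_noise
    mk_imu <- function(v, units) time_series(q9(v), fs = bp$fs_imu, t0 = 0,
                                             units = units)
    imu <- imu_recording(
      trunk_acc_v = mk_imu(sensor[1, ], "m/s^2"),
      trunk_acc_ml = mk_imu(sensor[2, ], "m/s^2"),
      trunk_acc_ap = mk_imu(sensor[3, ], "m/s^2"),
      shank_gyro_ml = mk_imu(sig$gyro(t_imu) + nz(n_imu, bp$noise_gyro),
                             "deg/s"),
      quiet_window = qw, task = bp$task)

    truth <- gait_events(apa_onset = tm$t_on, heel_off = tm$t_ho,
                         toe_off = tm$t_to, foot_contact = tm$t_fc,
                         trailing_toe_off = tm$t_tto, source = "ground_truth")
    list(fp = fp, imu = imu, truth = truth, blueprint = bp)
  })
}

#' Population model for synthetic cohorts
#'
#' Between-subject variability of the blueprint parameters.  Amplitudes
#' scale with a shared lognormal subject factor (CV ~ 0.42, matching the
#' between-subject spread reported for APA amplitudes); step climbing
#' scales a healthy subject's ML imbalance by a task factor ~ N(1.3,
#' 0.1), while the hypometric PD-like mode has no task scaling (factor
#' ~ N(1.0, 0.1)) and ML excursions scaled by 0.4 (imbalance) and 0.8
#' (unloading).
#'
#' @param group `"HC"` (healthy control) or `"PD"` (hypometric mode).
#' @export
cohort_population <- function(group = c("HC", "PD")) {
  group <- match.arg(group)
  list(group = group,
       amp_sdlog = 0.40, amp_range = c(0.35, 2.8),
       task_ratio_mean = if (group == "HC") 1.30 else 1.00,
       task_ratio_sd = 0.10,
       dur_imb_sd = 0.05, dur_unl_sd = 0.04, dur_swing_sd = 0.05,
       swing_scale = if (group == "HC") 1 else 0.88,
       trial_dur_sd = 0.02, trial_amp_sdlog = 0.05,
       omega_mean = 150, omega_sd = 20, omega_trial_sd = 5,
       k_ml_sdlog = 0.10,
       tilt_ap = c(5, 2), tilt_ml = c(2, 1),
       body_weight = c(700, 100))
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a cohort of paired synthetic trials
#'
#' Draws per-subject blueprint parameters from the population model and
#' generates `trials_per_subject` paired recordings per task for each
#' subject.  Deterministic under `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Repetitions per task (protocol default 3).
#' @param tasks Character vector of tasks to simulate.
#' @param group `"HC"` or `"PD"`.
#' @param seed Master RNG seed.
#' @param thresholds_true Optional named list (by task) of
#'   `apa_thresholds` at which the inertial crossings are aligned; when
#'   supplied, the onset alignment step for `A_true` is embedded in the
#'   trunk ML acceleration (calibration cohorts).
#' @param noise Optional named list overriding channel noise SDs
#'   (`cop`, `fz`, `acc`, `gyro`).
#' @param dir Optional directory: recordings, sidecars, ground-truth
#'   events and a `manifest.csv` are written there.
#' @return `list(trials, manifest)`: `trials` is a list of
#'   `list(subject, task, trial, group, fp, imu, truth, blueprint)`;
#'   `manifest` a `data.frame` (with file paths when `dir` is given).
#' @export
generate_cohort <- function(n_subjects, trials_per_subject = 3,
                            tasks = c("gait_initiation", "step_climbing"),
                            group = c("HC", "PD"), seed = 1,
                            thresholds_true = NULL, noise = NULL,
                            dir = NULL) {
  group <- match.arg(group)
  pop <- cohort_population(group)
  pd <- group == "PD"
  noise <- utils::modifyList(list(cop = 0.01, fz = 2, acc = 0.005, gyro = 0.5),
                             noise %||% list())
  trials <- with_seed(seed, {
    out <- list()
    for (s in seq_len(n_subjects)) {
      amp <- exp(stats::rnorm(1, 0, pop$amp_sdlog))
      amp <- pmin(pmax(amp, pop$amp_range[1]), pop$amp_range[2])
      task_ratio <- rtrunc_norm(1, pop$task_ratio_mean, pop$task_ratio_sd, 0.7, 2)
      k_ml <- 0.088 * exp(stats::rnorm(1, 0, pop$k_ml_sdlog))
      omega_s <- rtrunc_norm(1, pop$omega_mean, pop$omega_sd, 80, 260)
      tilt_ap <- stats::rnorm(1, pop$tilt_ap[1], pop$tilt_ap[2])
      tilt_ml <- stats::rnorm(1, pop$tilt_ml[1], pop$tilt_ml[2])
      bw <- rtrunc_norm(1, pop$body_weight[1], pop$body_weight[2], 400, 1100)
      dur_imb_s <- rtrunc_norm(1, 0.40, pop$dur_imb_sd, 0.28, 0.8)
      dur_unl_s <- rtrunc_norm(1, 0.30, pop$dur_unl_sd, 0.2, 0.6)
      ap_amp_s <- exp(stats::rnorm(1, 0, 0.3))
      for (task in tasks) {
        gait <- task == "gait_initiation"
        base_imb_ml <- 2.17 * amp * (if (pd) 0.4 else 1) *
          (if (gait) 1 else task_ratio)
        base_unl_ml <- -9.35 * amp * (if (pd) 0.8 else 1)
        base_swing <- (if (gait) 0.50 else 0.65) * pop$swing_scale
        dur_swing_s <- rtrunc_norm(1, base_swing, pop$dur_swing_sd, 0.3, 1.2)
        dur_imb_task <- dur_imb_s + (if (gait) 0 else 0.07)
        thr_true <- if (!is.null(thresholds_true)) thresholds_true[[task]]
                    else default_thresholds(task)
        marker_A <- if (!is.null(thresholds_true)) thr_true$A else NULL
        for (tr in seq_len(trials_per_subject)) {
          tseed <- sample.int(2147483646L, 1)
          jit <- function(x, sd, lo) max(x + stats::rnorm(1, 0, sd), lo)
          bp <- trial_blueprint(
            task = task,
            dur_imbalance = jit(dur_imb_task, pop$trial_dur_sd, 0.25),
            dur_unloading = jit(dur_unl_s, pop$trial_dur_sd, 0.18),
            dur_swing = jit(dur_swing_s, pop$trial_dur_sd, 0.3),
            imb_ml = base_imb_ml * exp(stats::rnorm(1, 0, pop$trial_amp_sdlog)),
            imb_ap = -2.0 * ap_amp_s,
            unl_ml = base_unl_ml * exp(stats::rnorm(1, 0, pop$trial_amp_sdlog)),
            k_ml = k_ml,
            omega_pk = rtrunc_norm(1, omega_s, pop$omega_trial_sd, 60, 300),
            thresholds_true = thr_true, onset_marker_A = marker_A,
            noise_cop = noise$cop, noise_fz = noise$fz,
            noise_acc = noise$acc, noise_gyro = noise$gyro,
            tilt_ap_deg = tilt_ap, tilt_ml_deg = tilt_ml,
            body_weight = bw, seed = tseed)
          out[[length(out) + 1L]] <- c(
            list(subject = sprintf("S%02d", s), task = task, trial = tr,
                 group = group),
            generate_trial(bp))
        }
      }
    }
    out
  })
  manifest <- data.frame(
    subject = vapply(trials, `[[`, character(1), "subject"),
    task = vapply(trials, `[[`, character(1), "task"),
    trial = vapply(trials, `[[`, numeric(1), "trial"),
    group = group, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      stub <- sprintf("%s_%s_t%d", tr$subject,
                      if (tr$task == "gait_initiation") "gait" else "step",
                      tr$trial)
      fp_csv <- file.path(dir, paste0(stub, "_fp.csv"))
      imu_csv <- file.path(dir, paste0(stub, "_imu.csv"))
      truth_json <- file.path(dir, paste0(stub, "_truth.json"))
      write_recording(tr$fp, fp_csv)
      write_recording(tr$imu, imu_csv)
      write_events(tr$truth, truth_json)
      c(fp_csv = fp_csv, imu_csv = imu_csv, truth_json = truth_json)
    })
    manifest$fp_csv <- vapply(paths, `[[`, character(1), "fp_csv")
    manifest$imu_csv <- vapply(paths, `[[`, character(1), "imu_csv")
    manifest$truth_json <- vapply(paths, `[[`, character(1), "truth_json")
    # the on-disk manifest carries paths relative to its own directory,
    # so a seeded cohort reproduces byte-for-byte wherever it is written
    disk <- manifest
    for (col in c("fp_csv", "imu_csv", "truth_json")) {
      disk[[col]] <- basename(disk[[col]])
    }
    utils::write.csv(disk, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(trials = trials, manifest = manifest)
}
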