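# Gold-standard event detection from force-plate COP and GRF signals.
#
# The COP trajectory (plate 1, 10 Hz zero-phase filtered) yields APA onset
# (threshold on the ML channel), and the leading-foot toe-off / heel-off
# through the geometry of the COP path: toe-off is the point of maximal
# perpendicular distance (d1_max) from the line L1 joining the COP at APA
# onset and at trailing-foot toe-off; heel-off is the point of maximal
# distance (d2_max) from the line L2 joining the COP at APA onset and at
# leading-foot toe-off.  Trailing toe-off comes from the decay of plate
# 1's vertical force and leading-foot contact from plate 2's force
# exceeding 6.5 % of body weight.

#' COP path (paired ML/AP trajectories)
#'
#' @param ml,ap COP channels as [time_series()] (cm), normally already
#'   low-pass filtered at 10 Hz.
#' @export
cop_path <- function(ml, ap) {
  check_aligned(list(ml, ap), "COP")
  structure(list(ml = ml, ap = ap), class = "apa_cop_path")
}

#' APA onset from the COP medio-lateral trajectory
#'
#' First sustained sample after the quiet window at which the ML COP
#' deviates from its quiet-standing mean by more than `sd_mult` times the
#' quiet-standing SD (default twice the SD).
#'
#' @param cop_ml ML COP as [time_series()] (cm), 10 Hz filtered.
#' @param quiet_window `c(start, end)` seconds of quiet standing.
#' @param sd_mult Threshold multiplier on the quiet-standing SD.
#' @param sustain_s Minimum time the excursion must hold (noise-spike
#'   rejection), default 25 ms.
#' @param abs_threshold Absolute threshold in cm, required for noiseless
#'   signals whose quiet-standing SD is zero.
#' @param refine If `TRUE`, refine the grid crossing by the smooth-step
#'   intercept fit (extrapolation of the initial rise back to baseline,
#'   removing the threshold latency).
#' @param refine_window_s Furthest the refinement may move the onset
#'   back from the crossing (s).
#' @param confirm_mult The accepted excursion must also reach this
#'   multiple of the threshold (two-threshold noise guard).
#' @return Onset time in seconds, with attributes `threshold`, `baseline`,
#'   `quiet_sd` and `t_cross` (the unrefined crossing).
#' @export
detect_onset_cop <- function(cop_ml, quiet_window, sd_mult = 2,
                             sustain_s = 0.025, abs_threshold = NULL,
                             refine = FALSE, refine_window_s = 0.2,
                             confirm_mult = 5) {
  detect_onset_core(cop_ml, quiet_window, sd_mult, sustain_s,
                    abs_threshold = abs_threshold, refine = refine,
                    refine_window_s = refine_window_s,
                    confirm_mult = confirm_mult, what = "COP ML")
}

#' Trailing-foot toe-off from plate 1's vertical force
#'
#' Time of the last sample at which `fz1` is still above a noise floor
#' (default 6.5 % of body weight, symmetric with contact detection) and
#' stays below it afterwards.
#'
#' @param fz1 Vertical GRF of plate 1 as [time_series()] (N).
#' @param body_weight Body weight in N.
#' @param floor_fraction Noise floor as a fraction of body weight.
#' @export
detect_trailing_toe_off <- function(fz1, body_weight, floor_fraction = 0.065) {
  thr <- floor_fraction * body_weight
  v <- fz1$values
  n <- length(v)
  if (v[n] >= thr || !any(v >= thr)) {
    apa_error("apa_no_liftoff_error",
              sprintf("fz1 never settles below the %.1f N noise floor", thr))
  }
  cand <- which(v >= thr)
  ts_times(fz1)[cand[length(cand)]]
}

# Perpendicular distances of the path points from the line through p0, p1.
point_line_distances <- function(ml, ap, p0, p1) {
  dx <- p1[1] - p0[1]
  dy <- p1[2] - p0[2]
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) {
    apa_error("apa_degenerate_line_error",
              "line endpoints coincide; COP line is undefined")
  }
  abs(dx * (ap - p0[2]) - dy * (ml - p0[1])) / len
}

max_distance_event <- function(path, t_start, t_end, t_line_end) {
  tt <- ts_times(path$ml)
  idx <- which(tt > t_start & tt < t_end)
  if (length(idx) == 0L) {
    apa_error("apa_detection_error",
              sprintf("no COP samples strictly inside (%.3f, %.3f) s", t_start, t_end))
  }
  p0 <- c(ts_at(path$ml, t_start), ts_at(path$ap, t_start))
  p1 <- c(ts_at(path$ml, t_line_end), ts_at(path$ap, t_line_end))
  d <- point_line_distances(path$ml$values[idx], path$ap$values[idx], p0, p1)
  k <- which.max(d)  # ties break to the earliest sample
  list(time = tt[idx[k]], d_max = d[k],
       degenerate = d[k] < 1e-9 * max(1, sqrt(sum((p1 - p0)^2))))
}

#' Leading-foot toe-off from COP geometry
#'
#' Among COP samples strictly between APA onset and trailing-foot
#' toe-off, the sample at maximal perpendicular distance (`d_max`,
#' a.k.a. d1_max) from the line through the COP positions at those two
#' instants.  Ties break to the earliest sample; a collinear path is
#' flagged `degenerate`.
#'
#' @param path A [cop_path()] (filtered).
#' @param t_onset,t_trailing_to APA onset and trailing toe-off (s).
#' @return `list(time, d_max, degenerate)`.
#' @export
detect_toe_off_cop <- function(path, t_onset, t_trailing_to) {
  if (!(t_onset < t_trailing_to)) {
    apa_error("apa_detection_error", "t_onset must precede t_trailing_to")
  }
  max_distance_event(path, t_onset, t_trailing_to, t_trailing_to)
}

#' Leading-foot heel-off from COP geometry
#'
#' Among COP samples strictly between APA onset and leading-foot toe-off,
#' the sample at maximal perpendicular distance (`d_max`, a.k.a. d2_max)
#' from the line through the COP positions at those two instants.
#'
#' @inheritParams detect_toe_off_cop
#' @param t_toe_off Leading-foot toe-off (s).
#' @return `list(time, d_max, degenerate)`.
#' @export
detect_heel_off_cop <- function(path, t_onset, t_toe_off) {
  if (!(t_onset < t_toe_off)) {
    apa_error("apa_detection_error", "t_onset must precede t_toe_off")
  }
  max_distance_event(path, t_onset, t_toe_off, t_toe_off)
}

#' Leading-foot contact from plate 2's vertical force
#'
#' First sample at which `fz2` exceeds `fraction` (default 6.5 %) of body
#' weight and stays above it for `sustain_s`.
#'
#' @param fz2 Vertical GRF of plate 2 as [time_series()] (N).
#' @param body_weight Body weight in N.
#' @param fraction Contact threshold as a fraction of body weight.
#' @param sustain_s Noise-spike rejection window.
#' @export
detect_foot_contact_grf <- function(fz2, body_weight, fraction = 0.065,
                                    sustain_s = 0.025) {
  thr <- fraction * body_weight
  n_sus <- max(1L, as.integer(round(sustain_s * fz2$fs)))
  i <- sustained_exceed(fz2$values, 1L, thr, n_sus)
  if (is.na(i)) {
    apa_error("apa_no_contact_error",
              sprintf("fz2 never exceeds the %.1f N contact threshold", thr))
  }
  ts_times(fz2)[i]
}

#' Filtered COP path of a force-plate recording
#'
#' @param rec An `apa_fp_recording`.
#' @param cutoff Low-pass cutoff in Hz (default 10).
#' @export
fp_cop_path <- function(rec, cutoff = 10) {
  spec <- filter_spec(cutoff)
  cop_path(zero_phase_lowpass(rec$cop1_ml, spec),
           zero_phase_lowpass(rec$cop1_ap, spec))
}

#' Full force-plate event detection for one trial
#'
#' Filters the COP at 10 Hz (zero-phase) and runs the detectors in
#' dependency order: APA onset (2 SD on ML COP), trailing toe-off (plate 1
#' force decay), leading toe-off (d1_max from line L1), heel-off (d2_max
#' from line L2), and leading-foot contact (6.5 % body weight on plate 2).
#'
#' @param rec An `apa_fp_recording`.
#' @param sd_mult Onset threshold multiplier (default 2).
#' @param fc_fraction GRF contact / lift-off fraction of body weight.
#' @param cutoff COP filter cutoff in Hz.
#' @param refine_onset Refine the onset crossing by the smooth-step
#'   intercept fit (default `TRUE`).
#' @param abs_onset_threshold Absolute onset threshold in cm for noiseless
#'   recordings.
#' @return An `apa_events` object (`source = "force_plate"`) with a
#'   `diagnostics` attribute carrying d1_max, d2_max, the onset threshold
#'   and degeneracy flags.
#' @export
detect_all_fp <- function(rec, sd_mult = 2, fc_fraction = 0.065, cutoff = 10,
                          refine_onset = TRUE, abs_onset_threshold = NULL) {
  path <- fp_cop_path(rec, cutoff)
  onset <- detect_onset_cop(path$ml, rec$quiet_window, sd_mult = sd_mult,
                            abs_threshold = abs_onset_threshold,
                            refine = refine_onset)
  t_tto <- detect_trailing_toe_off(rec$fz1, rec$body_weight,
                                   floor_fraction = fc_fraction)
  toe <- detect_toe_off_cop(path, as.numeric(onset), t_tto)
  heel <- detect_heel_off_cop(path, as.numeric(onset), toe$time)
  t_fc <- detect_foot_contact_grf(rec$fz2, rec$body_weight,
                                  fraction = fc_fraction)
  ev <- gait_events(apa_onset = as.numeric(onset), heel_off = heel$time,
                    toe_off = toe$time, foot_contact = t_fc,
                    trailing_toe_off = t_tto, source = "force_plate")
  attr(ev, "diagnostics") <- list(
    d1_max = toe$d_max, d2_max = heel$d_max,
    toe_off_degenerate = toe$degenerate, heel_off_degenerate = heel$degenerate,
    onset_threshold = attr(onset, "threshold"),
    onset_crossing = attr(onset, "t_cross"))
  apa_log("FP events: onset %.3f heel %.3f toe %.3f contact %.3f trailingTO %.3f (d1 %.2f, d2 %.2f cm)",
          ev$apa_onset, ev$heel_off, ev$toe_off, ev$foot_contact,
          ev$trailing_toe_off, toe$d_max, heel$d_max)
  ev
}
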