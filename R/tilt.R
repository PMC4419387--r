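#' @keywords internal
#' Standard gravity used for tilt correction (m/s^2).
GRAVITY <- 9.80665

# Two-step tilt rotation: first about the ML axis by theta (AP tilt), then
# about the rotated AP axis by phi (ML tilt).  Axis order is (v, ml, ap).
tilt_rotation <- function(theta, phi) {
  R1 <- rbind(c(cos(theta), 0, sin(theta)),
              c(0, 1, 0),
              c(-sin(theta), 0, cos(theta)))
  R2 <- rbind(c(cos(phi), sin(phi), 0),
              c(-sin(phi), cos(phi), 0),
              c(0, 0, 1))
  R2 %*% R1
}

# Tilt angles (theta = AP tilt, phi = ML tilt) from mean quiet-standing
# accelerations in the sensor frame.
tilt_estimate <- function(mean_v, mean_ml, mean_ap) {
  theta <- atan2(mean_ap, mean_v)
  v1 <- cos(theta) * mean_v + sin(theta) * mean_ap
  phi <- atan2(mean_ml, v1)
  c(theta = theta, phi = phi)
}

#' Tilt correction of trunk accelerations (Moe-Nilssen transformation)
#'
#' Estimates the static tilt of the trunk sensor from its mean
#' accelerations during the quiet-standing window (when the only sensed
#' acceleration is gravity), rotates the acceleration triplet into a
#' horizontal-vertical frame, and removes gravity from the vertical
#' channel.  After correction the quiet-window means of all three outputs
#' are approximately zero.
#'
#' The tilt is estimated in two inverse-trigonometric steps: the AP tilt
#' angle about the ML axis from the AP/vertical means, then the ML tilt
#' about the corrected AP axis.  Gravity is taken as 9.80665 m/s^2.
#'
#' @param trunk_acc_v,trunk_acc_ml,trunk_acc_ap Sensor-frame acceleration
#'   channels as [time_series()] (m/s^2).
#' @param quiet_window `c(start, end)` seconds of quiet standing.
#' @return A list with corrected `trunk_acc_v`, `trunk_acc_ml`,
#'   `trunk_acc_ap` (gravity removed) and the estimated `angles`
#'   (radians).
#' @export
tilt_correct <- function(trunk_acc_v, trunk_acc_ml, trunk_acc_ap, quiet_window) {
  series <- list(trunk_acc_v, trunk_acc_ml, trunk_acc_ap)
  check_aligned(series, "acceleration")
  idx <- ts_window_idx(trunk_acc_v, quiet_window[1], quiet_window[2])
  if (length(idx) < 2L) {
    apa_error("apa_schema_error", "quiet_window contains fewer than 2 samples")
  }
  m <- c(mean(trunk_acc_v$values[idx]),
         mean(trunk_acc_ml$values[idx]),
         mean(trunk_acc_ap$values[idx]))
  mag <- sqrt(sum(m^2))
  if (mag < 0.5 * GRAVITY || mag > 1.5 * GRAVITY) {
    apa_error("apa_calibration_error",
              sprintf("quiet-window acceleration magnitude %.2f m/s^2 is implausible for a static trunk sensor (expected within [%.2f, %.2f]); check sensor placement",
                      mag, 0.5 * GRAVITY, 1.5 * GRAVITY))
  }
  ang <- tilt_estimate(m[1], m[2], m[3])
  R <- tilt_rotation(ang["theta"], ang["phi"])
  X <- rbind(trunk_acc_v$values, trunk_acc_ml$values, trunk_acc_ap$values)
  Y <- R %*% X
  Y[1, ] <- Y[1, ] - GRAVITY
  mk <- function(row, ref) time_series(Y[row, ], fs = ref$fs, t0 = ref$t0,
                                       units = ref$units)
  list(trunk_acc_v = mk(1, trunk_acc_v),
       trunk_acc_ml = mk(2, trunk_acc_ml),
       trunk_acc_ap = mk(3, trunk_acc_ap),
       angles = ang)
}
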