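#' Force-plate recording of one trial
#'
#' Two-plate setup: the subject stands with both feet on plate 1 and steps
#' onto plate 2.  Plate 1 provides the COP trajectory (medio-lateral and
#' antero-posterior, cm) and its vertical ground reaction force `fz1` (N);
#' plate 2 provides `fz2` (N), used for leading-foot contact detection.
#'
#' Sign conventions: the ML axis is positive toward the stepping (leading)
#' side and the AP axis positive forward, so the imbalance-phase ML
#' excursion is positive and the unloading-phase ML excursion negative.
#'
#' @param cop1_ml,cop1_ap COP of plate 1 as [time_series()] in cm.
#' @param fz1,fz2 Vertical GRF of plates 1 and 2 as [time_series()] in N.
#' @param body_weight Body weight in N (> 0).
#' @param quiet_window `c(start, end)` seconds of quiet standing preceding
#'   any movement; must be at least 1 s long.
#' @param task `"gait_initiation"` or `"step_climbing"`.
#' @param stepping_side `"right"` or `"left"`.
#' @return An object of class `apa_fp_recording`.
#' @export
force_plate_recording <- function(cop1_ml, cop1_ap, fz1, fz2, body_weight,
                                  quiet_window, task = "gait_initiation",
                                  stepping_side = "right") {
  series <- list(cop1_ml = cop1_ml, cop1_ap = cop1_ap, fz1 = fz1, fz2 = fz2)
  for (nm in names(series)) {
    if (!is_time_series(series[[nm]])) {
      apa_error("apa_schema_error", sprintf("'%s' must be a time_series", nm),
                field = nm)
    }
  }
  check_aligned(series, "force-plate")
  stopifnot_scalar_number(body_weight, "body_weight", positive = TRUE)
  check_quiet_window(quiet_window, cop1_ml)
  task <- match.arg(task, c("gait_initiation", "step_climbing"))
  stepping_side <- match.arg(stepping_side, c("right", "left"))
  structure(c(series,
              list(body_weight = body_weight, quiet_window = quiet_window,
                   task = task, stepping_side = stepping_side)),
            class = "apa_fp_recording")
}

#' Inertial (IMU) recording of one trial
#'
#' Lower-trunk (L2-L4) triaxial acceleration in the sensor frame (m/s^2;
#' the vertical channel reads +g when upright and static) and the angular
#' velocity of the leading-leg shank about its medio-lateral axis (deg/s).
#'
#' @param trunk_acc_v,trunk_acc_ml,trunk_acc_ap Trunk acceleration channels
#'   as [time_series()] in m/s^2.
#' @param shank_gyro_ml Shank ML angular velocity as [time_series()] in deg/s.
#' @inheritParams force_plate_recording
#' @return An object of class `apa_imu_recording`.
#' @export
imu_recording <- function(trunk_acc_v, trunk_acc_ml, trunk_acc_ap,
                          shank_gyro_ml, quiet_window,
                          task = "gait_initiation", stepping_side = "right") {
  series <- list(trunk_acc_v = trunk_acc_v, trunk_acc_ml = trunk_acc_ml,
                 trunk_acc_ap = trunk_acc_ap, shank_gyro_ml = shank_gyro_ml)
  for (nm in names(series)) {
    if (!is_time_series(series[[nm]])) {
      apa_error("apa_schema_error", sprintf("'%s' must be a time_series", nm),
                field = nm)
    }
  }
  check_aligned(series, "IMU")
  check_quiet_window(quiet_window, trunk_acc_ml)
  task <- match.arg(task, c("gait_initiation", "step_climbing"))
  stepping_side <- match.arg(stepping_side, c("right", "left"))
  structure(c(series,
              list(quiet_window = quiet_window, task = task,
                   stepping_side = stepping_side)),
            class = "apa_imu_recording")
}

check_quiet_window <- function(qw, ref) {
  if (!is.numeric(qw) || length(qw) != 2L || !all(is.finite(qw))) {
    apa_error("apa_schema_error", "quiet_window must be c(start, end) seconds",
              field = "quiet_window")
  }
  if (qw[2] - qw[1] < 1) {
    apa_error("apa_schema_error", "quiet_window must be at least 1 s long",
              field = "quiet_window")
  }
  if (qw[1] < ref$t0 - 0.5 / ref$fs || qw[2] > ts_end(ref) + 0.5 / ref$fs) {
    apa_error("apa_schema_error", "quiet_window lies outside the record",
              field = "quiet_window")
  }
  invisible(TRUE)
}

#' @export
print.apa_fp_recording <- function(x, ...) {
  cat(sprintf(
    "<force-plate recording> %s, %s foot leading, %.1f N, %g Hz, %.2f s\n",
    x$task, x$stepping_side, x$body_weight, x$cop1_ml$fs,
    length(x$cop1_ml$values) / x$cop1_ml$fs))
  invisible(x)
}

#' @export
print.apa_imu_recording <- function(x, ...) {
  cat(sprintf("<IMU recording> %s, %s foot leading, %g Hz, %.2f s\n",
              x$task, x$stepping_side, x$trunk_acc_ml$fs,
              length(x$trunk_acc_ml$values) / x$trunk_acc_ml$fs))
  invisible(x)
}
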