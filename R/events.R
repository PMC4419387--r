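#' Gait-initiation / step-climbing events of one trial
#'
#' The five instants that segment the transition from quiet standing into
#' the first step: APA onset, heel-off, toe-off and foot contact of the
#' leading foot, plus (when available, i.e. from force plates) the toe-off
#' of the trailing foot.  Times are continuous seconds from recording
#' start.  The required ordering is
#' `apa_onset <= heel_off <= toe_off <= foot_contact` and, when present,
#' `toe_off <= trailing_toe_off`.
#'
#' @param apa_onset,heel_off,toe_off,foot_contact Event times in seconds.
#' @param trailing_toe_off Trailing-foot toe-off in seconds, or `NA`.
#' @param source One of `"force_plate"`, `"imu"`, `"ground_truth"`.
#' @return An object of class `apa_events`.
#' @export
gait_events <- function(apa_onset, heel_off, toe_off, foot_contact,
                        trailing_toe_off = NA_real_,
                        source = c("force_plate", "imu", "ground_truth")) {
  source <- match.arg(source)
  ev <- list(apa_onset = apa_onset, heel_off = heel_off, toe_off = toe_off,
             foot_contact = foot_contact,
             trailing_toe_off = as.numeric(trailing_toe_off), source = source)
  for (nm in c("apa_onset", "heel_off", "toe_off", "foot_contact")) {
    stopifnot_scalar_number(ev[[nm]], nm)
  }
  check_event_order(ev)
  structure(ev, class = "apa_events")
}

check_event_order <- function(ev) {
  tol <- 1e-9
  ok <- ev$apa_onset <= ev$heel_off + tol &&
    ev$heel_off <= ev$toe_off + tol &&
    ev$toe_off <= ev$foot_contact + tol
  if (ok && is.finite(ev$trailing_toe_off)) {
    ok <- ev$toe_off <= ev$trailing_toe_off + tol
  }
  if (!ok) {
    apa_error("apa_integrity_error",
              "event times violate the required ordering apa_onset <= heel_off <= toe_off <= foot_contact (<= trailing_toe_off)")
  }
  invisible(TRUE)
}

event_names <- function() {
  c("apa_onset", "heel_off", "toe_off", "foot_contact", "trailing_toe_off")
}

#' @export
print.apa_events <- function(x, ...) {
  cat(sprintf(
    "<events:%s> onset %.3f | heel-off %.3f | toe-off %.3f | contact %.3f | trailing TO %s\n",
    x$source, x$apa_onset, x$heel_off, x$toe_off, x$foot_contact,
    if (is.finite(x$trailing_toe_off)) sprintf("%.3f", x$trailing_toe_off) else "-"))
  invisible(x)
}

#' @export
as.data.frame.apa_events <- function(x, ...) {
  data.frame(apa_onset = x$apa_onset, heel_off = x$heel_off,
             toe_off = x$toe_off, foot_contact = x$foot_contact,
             trailing_toe_off = x$trailing_toe_off, source = x$source,
             stringsAsFactors = FALSE)
}

#' Detector threshold set for the inertial method
#'
#' `A` multiplies the quiet-standing SD of trunk ML acceleration for APA
#' onset detection; `H` and `T` are fractions of the first shank
#' angular-velocity peak used for heel-off and toe-off;
#' `fc_grf_fraction` is the body-weight fraction used for foot-contact
#' (and trailing toe-off) detection on the force plates.
#'
#' @param A Onset multiplier (>= 0).
#' @param H Heel-off fraction in `[0, 1]`.
#' @param T_ Toe-off fraction in `[0, 1]`.
#' @param fc_grf_fraction GRF contact threshold as a fraction of body weight.
#' @return An object of class `apa_thresholds`.
#' @export
thresholds <- function(A, H, T_, fc_grf_fraction = 0.065) {
  if (!is.numeric(A) || A < 0) apa_error("apa_schema_error", "A must be >= 0")
  if (!is.numeric(H) || H < 0 || H > 1) {
    apa_error("apa_schema_error", "H must lie in [0, 1]")
  }
  if (!is.numeric(T_) || T_ < 0 || T_ > 1) {
    apa_error("apa_schema_error", "T must lie in [0, 1]")
  }
  if (fc_grf_fraction <= 0 || fc_grf_fraction >= 1) {
    apa_error("apa_schema_error", "fc_grf_fraction must lie in (0, 1)")
  }
  structure(list(A = A, H = H, T = T_, fc_grf_fraction = fc_grf_fraction),
            class = "apa_thresholds")
}

#' Calibrated default thresholds per task
#'
#' Gait initiation: A = 2, H = 0.07, T = 0.25.  Step climbing: A = 2,
#' H = 0.08, T = 1.  Foot contact uses 6.5 % of body weight for both.
#'
#' @param task `"gait_initiation"` or `"step_climbing"`.
#' @export
default_thresholds <- function(task = c("gait_initiation", "step_climbing")) {
  task <- match.arg(task)
  if (task == "gait_initiation") thresholds(A = 2, H = 0.07, T_ = 0.25)
  else thresholds(A = 2, H = 0.08, T_ = 1)
}
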