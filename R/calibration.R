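# Grid-search calibration of the inertial thresholds A, H, T against
# force-plate events, and mean-absolute-error reporting.
#
# The factors are optimized sequentially over the published grid
# (A in 1..5 step 1, H in 0..1 step 0.01, T in 0..1 step 0.05): A
# minimizes the across-subject averaged APA-onset MAE; given the selected
# A (which fixes the onset and hence the gyro landmark search), H
# minimizes the heel-off MAE and T the toe-off MAE.  Toe-off is
# independent of A and H by construction, and heel-off depends on the
# onset, which motivates the A -> H -> T order; ties break toward the
# smallest factor.  Foot contact has no free parameter; its MAE is
# reported but not optimized.

#' Per-event mean absolute error between two event sources
#'
#' Per-trial absolute differences are averaged within subjects and then
#' across subjects.  The percentage error refers each subject's MAE to
#' that subject's mean force-plate step duration (APA onset to foot
#' contact).  Pairs missing an event are excluded with a warning.
#'
#' @param pairs List of `list(fp = apa_events, imu = apa_events,
#'   subject = id)` entries (one per trial).
#' @return A `data.frame` with `event`, `mae_s`, `pct_step`, `n_trials`,
#'   `n_excluded`.
#' @export
mae_per_event <- function(pairs) {
  if (!length(pairs)) {
    apa_error("apa_insufficient_data_error", "no event pairs supplied")
  }
  evs <- c("apa_onset", "heel_off", "toe_off", "foot_contact")
  rows <- lapply(evs, function(e) {
    err <- vapply(pairs, function(p) {
      a <- p$fp[[e]]
      b <- p$imu[[e]]
      if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b)) {
        NA_real_
      } else abs(b - a)
    }, numeric(1))
    step_dur <- vapply(pairs, function(p) {
      p$fp$foot_contact - p$fp$apa_onset
    }, numeric(1))
    subj <- vapply(pairs, function(p) as.character(p$subject %||% "s"),
                   character(1))
    drop <- is.na(err)
    if (any(drop)) {
      warning(sprintf("%d pair(s) missing event '%s' excluded from the MAE",
                      sum(drop), e), call. = FALSE)
    }
    per_subj_mae <- tapply(err[!drop], subj[!drop], mean)
    per_subj_dur <- tapply(step_dur[!drop], subj[!drop], mean)
    data.frame(event = e,
               mae_s = mean(per_subj_mae),
               pct_step = mean(100 * per_subj_mae / per_subj_dur),
               n_trials = sum(!drop), n_excluded = sum(drop))
  })
  do.call(rbind, rows)
}

#' Default calibration grid
#' @export
default_grid <- function() {
  list(A = 1:5, H = seq(0, 1, by = 0.01), T = seq(0, 1, by = 0.05))
}

#' Calibrate the inertial thresholds against force-plate events
#'
#' @param pairs List of paired trials: each element
#'   `list(imu_rec = apa_imu_recording, fp_events = apa_events,
#'   subject = id)`; recordings must be temporally aligned with the
#'   force-plate trial (common time axis).
#' @param grid Named list of candidate values for `A`, `H`, `T`
#'   ([default_grid()] reproduces the published search ranges).
#' @param cutoff Filter cutoff in Hz for the inertial signals.
#' @param interp Sub-sample interpolation of gyro/acceleration crossings.
#' @return An object of class `apa_calibration`: `best`
#'   (`apa_thresholds`), the four per-event MAEs at the optimum (seconds),
#'   and `grid`, a `data.frame` of every evaluated grid point with its
#'   averaged MAE (the audit surface).
#' @export
calibrate <- function(pairs, grid = default_grid(), cutoff = 3.5,
                      interp = TRUE) {
  if (!length(pairs)) {
    apa_error("apa_insufficient_data_error", "no paired trials supplied")
  }
  prepped <- lapply(pairs, function(p) {
    prep <- imu_preprocess(p$imu_rec, cutoff)
    list(acc_ml = prep$acc_ml, gyro = prep$gyro,
         quiet_window = p$imu_rec$quiet_window,
         fp = p$fp_events, subject = as.character(p$subject %||% "s"))
  })
  subj <- vapply(prepped, function(p) p$subject, character(1))

  avg_mae <- function(err) {
    ok <- is.finite(err)
    if (!any(ok)) return(Inf)
    mean(tapply(err[ok], subj[ok], mean))
  }
  # Stage 1: A (onset)
  onset_for_A <- function(A) {
    vapply(prepped, function(p) {
      tryCatch(as.numeric(detect_onset_imu(p$acc_ml, p$quiet_window, A = A,
                                           interp = interp)),
               apa_error = function(e) NA_real_)
    }, numeric(1))
  }
  surf_A <- lapply(grid$A, function(A) {
    on <- onset_for_A(A)
    err <- abs(on - vapply(prepped, function(p) p$fp$apa_onset, numeric(1)))
    list(A = A, mae = avg_mae(err), onsets = on)
  })
  mae_A <- vapply(surf_A, `[[`, numeric(1), "mae")
  if (all(!is.finite(mae_A))) {
    apa_error("apa_calibration_error",
              "onset detection failed on every trial for every A")
  }
  iA <- which.min(mae_A)  # ties -> smallest factor (grid is ascending)
  A_best <- grid$A[iA]
  onsets <- surf_A[[iA]]$onsets

  # Gyro landmarks at the selected A
  feats <- lapply(seq_along(prepped), function(i) {
    if (!is.finite(onsets[i])) return(NULL)
    tryCatch(extract_gyro_features(prepped[[i]]$gyro, onsets[i]),
             apa_error = function(e) NULL)
  })
  usable <- !vapply(feats, is.null, logical(1))
  if (!any(usable)) {
    apa_error("apa_calibration_error",
              "gyro landmark extraction failed on every trial")
  }
  if (any(!usable)) {
    warning(sprintf("%d trial(s) without usable gyro landmarks excluded",
                    sum(!usable)), call. = FALSE)
  }

  # Stage 2: H (heel-off)
  surf_H <- vapply(grid$H, function(H) {
    err <- vapply(seq_along(prepped), function(i) {
      if (!usable[i]) return(NA_real_)
      t <- tryCatch(
        detect_heel_off_imu(prepped[[i]]$gyro, onsets[i], feats[[i]], H,
                            interp = interp),
        apa_error = function(e) NA_real_)
      abs(t - prepped[[i]]$fp$heel_off)
    }, numeric(1))
    avg_mae(err)
  }, numeric(1))
  iH <- which.min(surf_H)
  H_best <- grid$H[iH]

  # Stage 3: T (toe-off)
  surf_T <- vapply(grid$T, function(T_) {
    err <- vapply(seq_along(prepped), function(i) {
      if (!usable[i]) return(NA_real_)
      t <- tryCatch(
        detect_toe_off_imu(prepped[[i]]$gyro, feats[[i]], T_, interp = interp),
        apa_error = function(e) NA_real_)
      abs(t - prepped[[i]]$fp$toe_off)
    }, numeric(1))
    avg_mae(err)
  }, numeric(1))
  iT <- which.min(surf_T)
  T_best <- grid$T[iT]

  # Foot contact (no free parameter)
  err_fc <- vapply(seq_along(prepped), function(i) {
    if (!usable[i]) return(NA_real_)
    abs(as.numeric(detect_foot_contact_imu(feats[[i]])) -
          prepped[[i]]$fp$foot_contact)
  }, numeric(1))

  surface <- rbind(
    data.frame(factor = "A", value = grid$A, event = "apa_onset", mae = mae_A),
    data.frame(factor = "H", value = grid$H, event = "heel_off", mae = surf_H),
    data.frame(factor = "T", value = grid$T, event = "toe_off", mae = surf_T))
  res <- structure(list(
    best = thresholds(A = A_best, H = H_best, T_ = T_best),
    mae_onset = mae_A[iA], mae_heel_off = surf_H[iH],
    mae_toe_off = surf_T[iT], mae_foot_contact = avg_mae(err_fc),
    grid = surface, n_trials = sum(usable)), class = "apa_calibration")
  apa_log("calibrated A=%g H=%g T=%g (MAEs %.3f/%.3f/%.3f/%.3f s)",
          A_best, H_best, T_best, res$mae_onset, res$mae_heel_off,
          res$mae_toe_off, res$mae_foot_contact)
  res
}

#' Re-scan a stored calibration surface for its per-event optima
#'
#' Exhaustively re-derives the minimizing factor of each event's MAE from
#' the audit surface; used to verify that [calibrate()] returned global
#' per-event minimizers.
#'
#' @param result An `apa_calibration`.
#' @return Named list `A`, `H`, `T` of re-derived optima.
#' @export
calibration_rescan <- function(result) {
  g <- result$grid
  pick <- function(f) {
    s <- g[g$factor == f, ]
    s$value[which.min(s$mae)]
  }
  list(A = pick("A"), H = pick("H"), T = pick("T"))
}

#' @export
print.apa_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> A = %g, H = %g, T = %g over %d trials\n  MAE: onset %.3f s, heel-off %.3f s, toe-off %.3f s, contact %.3f s\n",
    x$best$A, x$best$H, x$best$T, x$n_trials, x$mae_onset, x$mae_heel_off,
    x$mae_toe_off, x$mae_foot_contact))
  invisible(x)
}
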