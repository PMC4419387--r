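# Shared threshold-onset machinery for COP and trunk-acceleration channels.
#
# Onset is the first sustained excursion of |x - baseline mean| beyond a
# threshold (a multiple of the quiet-standing SD, or an absolute level for
# noiseless signals).  Optionally the grid-time crossing is refined by
# extrapolating the initial rise back to baseline (see
# refine_onset_sqrt below), which removes the threshold-latency bias of
# plain crossing detectors (a smooth movement takes
# sqrt(threshold / curvature) seconds to reach the threshold after it
# truly starts).

detect_onset_core <- function(x, quiet_window, sd_mult, sustain_s,
                              abs_threshold = NULL, refine = FALSE,
                              refine_window_s = 0.1, confirm_mult = 5,
                              interp = FALSE, what = "signal") {
  idx_q <- ts_window_idx(x, quiet_window[1], quiet_window[2])
  if (length(idx_q) < 2L) {
    apa_error("apa_schema_error", "quiet_window contains fewer than 2 samples")
  }
  baseline <- mean(x$values[idx_q])
  s <- stats::sd(x$values[idx_q])
  if (is.null(abs_threshold)) {
    if (s <= .Machine$double.eps^0.5 * max(1, abs(baseline))) {
      apa_error("apa_degenerate_baseline_error",
                sprintf("quiet-standing SD of %s is zero; supply an absolute threshold (abs_threshold) for noiseless signals",
                        what))
    }
    threshold <- sd_mult * s
  } else {
    stopifnot_scalar_number(abs_threshold, "abs_threshold", positive = TRUE)
    threshold <- abs_threshold
  }
  dev <- abs(x$values - baseline)
  tt <- ts_times(x)
  start <- which(tt > quiet_window[2])[1]
  if (is.na(start)) {
    apa_error("apa_no_onset_error", "no samples after the quiet window")
  }
  n_sus <- max(1L, as.integer(round(sustain_s * x$fs)))
  # scale-free guard against the pre-onset ringing of zero-phase
  # filtering: an accepted excursion must also climb to a few percent of
  # the post-quiet maximum deviation.  Ringing lobes reach 1-3 % of the
  # nearby movement, while even a strongly hypometric imbalance phase
  # reaches >= 13 % of the overall excursion.
  peak_floor <- 0.06 * max(dev[start:length(dev)])
  i0 <- sustained_exceed(dev, start, threshold, n_sus,
                         confirm = confirm_mult, min_peak = peak_floor)
  if (is.na(i0)) {
    apa_error("apa_no_onset_error",
              sprintf("%s never exceeds the onset threshold (%.4g) after the quiet window",
                      what, threshold))
  }
  t_cross <- if (interp) interp_crossing(dev, tt, i0, threshold) else tt[i0]
  t_onset <- if (refine) {
    refine_onset_sqrt(dev, tt, i0, x$fs, refine_window_s,
                      min_amp = peak_floor)
  } else {
    t_cross
  }
  structure(t_onset,
            threshold = threshold, baseline = baseline, quiet_sd = s,
            t_cross = t_cross)
}

# First index >= start opening an excursion of v above thr that (a)
# lasts at least n_sus samples (or reaches the end of the record) and
# (b) peaks at or above confirm * thr.  The confirmation level is the
# classic two-threshold guard against slow, autocorrelated noise (after
# low-pass filtering, noise excursions beyond the detection threshold
# can easily outlast a fixed hold time, but they rarely climb much
# higher; a true movement onset does).
sustained_exceed <- function(v, start, thr, n_sus, confirm = 1, min_peak = 0) {
  n <- length(v)
  above <- v > thr
  if (start > 1L) above[seq_len(start - 1L)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  floor_k <- max(confirm * thr, min_peak)
  for (k in which(r$values)) {
    long_enough <- r$lengths[k] >= n_sus || ends[k] == n
    if (long_enough && max(v[begins[k]:ends[k]]) >= floor_k) {
      return(begins[k])
    }
  }
  NA_integer_
}

# Smooth-step intercept onset refinement.  A threshold crossing lags the
# true movement start by the time the excursion needs to reach the
# threshold; for the smooth (minimum-jerk-like) rises of APA excursions
# the deviation follows dev(t) ~ Amp * sin^2(k (t - t_onset)) closely,
# so z = asin(sqrt(dev / Amp)) is linear in t and the x-intercept of a
# straight-line fit to z estimates the onset without that latency bias.
# Amp is taken as the first local maximum of the deviation after the
# crossing (the imbalance-phase extreme) that clears `min_amp` (so that
# noise or filter-ringing wiggles near the crossing are not mistaken
# for the movement peak); the fit uses the rise up to 75 % of Amp,
# where the transform is well conditioned.
refine_onset_sqrt <- function(dev, tt, i0, fs, max_back_s = 0.35,
                              min_amp = 0) {
  n <- length(dev)
  run_max <- dev[i0]
  imax <- i0
  i <- i0
  horizon <- min(n, i0 + as.integer(round(2 * fs)))
  while (i < horizon) {
    i <- i + 1L
    if (dev[i] > run_max) {
      run_max <- dev[i]
      imax <- i
    } else if (run_max >= min_amp && dev[i] < 0.93 * run_max) break
  }
  amp <- run_max
  # fit on the 4-75 % band of the rise: below 4 % the deviation is
  # noise / filter ringing, above 75 % the transform is ill-conditioned
  sel <- i0:imax
  sel <- sel[dev[sel] <= 0.75 * amp & dev[sel] >= 0.04 * amp]
  if (length(sel) < 4L || amp <= 0) return(tt[i0])
  z <- asin(sqrt(pmin(pmax(dev[sel] / amp, 0), 1)))
  fit <- stats::lm.fit(cbind(1, tt[sel]), z)
  cf <- fit$coefficients
  if (!is.finite(cf[2]) || cf[2] <= 0) return(tt[i0])
  intercept <- -cf[1] / cf[2]
  # the crossing may itself sit early on a ringing lobe, so the refined
  # onset may move forward of it (never past the fitted rise)
  min(max(intercept, tt[i0] - max_back_s), tt[imax])
}

# Refine a detected onset on a companion (typically wider-band) series:
# baseline from the quiet window, then the sqrt-intercept fit starting
# at the sample nearest the detected crossing.
refine_onset_on <- function(x, quiet_window, t_cross, max_back_s = 0.35) {
  idx_q <- ts_window_idx(x, quiet_window[1], quiet_window[2])
  dev <- abs(x$values - mean(x$values[idx_q]))
  tt <- ts_times(x)
  i0 <- ts_index(x, t_cross)
  start <- which(tt > quiet_window[2])[1]
  floor_amp <- 0.06 * max(dev[start:length(dev)])
  refine_onset_sqrt(dev, tt, i0, x$fs, max_back_s, min_amp = floor_amp)
}

# Linear-interpolated upward crossing time of level thr between samples
# i-1 and i (falls back to the sample time at window starts).
interp_crossing <- function(values, tt, i, thr) {
  if (i <= 1L) return(tt[i])
  v0 <- values[i - 1L]
  v1 <- values[i]
  if ((v1 - v0) == 0) return(tt[i])
  f <- (thr - v0) / (v1 - v0)
  if (!is.finite(f) || f < 0 || f > 1) return(tt[i])
  tt[i - 1L] + f * (tt[i] - tt[i - 1L])
}
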