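# Spatio-temporal APA parameters and the validation / group-comparison
# statistics.
#
# Temporal parameters: imbalance = heel_off - apa_onset, unloading =
# toe_off - heel_off, APA = imbalance + unloading, swing = foot_contact -
# toe_off, step = APA + swing.  Spatial parameters are signal differences
# at the event instants (COP position in cm for the force plate, trunk
# acceleration in m/s^2 for the wearable system), evaluated at the sample
# nearest to each event time.

#' Phase durations from detected events
#'
#' @param events An `apa_events` object (ordering already validated).
#' @return Named numeric vector: `dur_imbalance`, `dur_unloading`,
#'   `dur_apa`, `dur_swing`, `dur_step` (seconds).  The identities
#'   `dur_apa = dur_imbalance + dur_unloading` and
#'   `dur_step = dur_apa + dur_swing` hold exactly.
#' @export
compute_durations <- function(events) {
  if (!inherits(events, "apa_events")) {
    apa_error("apa_schema_error", "events must be an apa_events object")
  }
  check_event_order(events)
  imb <- events$heel_off - events$apa_onset
  unl <- events$toe_off - events$heel_off
  swing <- events$foot_contact - events$toe_off
  c(dur_imbalance = imb, dur_unloading = unl, dur_apa = imb + unl,
    dur_swing = swing, dur_step = imb + unl + swing)
}

#' Phase amplitudes from ML/AP signals at the event instants
#'
#' Imbalance amplitude = value at heel-off minus value at APA onset;
#' unloading amplitude = value at toe-off minus value at heel-off.  The
#' same code path serves COP displacements (cm) and trunk accelerations
#' (m/s^2); values are taken at the sample nearest each event time.
#'
#' @param signal_ml,signal_ap ML and AP channels as [time_series()]
#'   (filtered, consistent with detection).
#' @param events An `apa_events` object whose onset/heel-off/toe-off lie
#'   inside the record.
#' @return Named numeric vector: `amp_imbalance_ml`, `amp_imbalance_ap`,
#'   `amp_unloading_ml`, `amp_unloading_ap`.
#' @export
compute_amplitudes <- function(signal_ml, signal_ap, events) {
  check_aligned(list(signal_ml, signal_ap), "ML/AP")
  v <- function(s, t) ts_at(s, t, check = TRUE)
  c(amp_imbalance_ml = v(signal_ml, events$heel_off) - v(signal_ml, events$apa_onset),
    amp_imbalance_ap = v(signal_ap, events$heel_off) - v(signal_ap, events$apa_onset),
    amp_unloading_ml = v(signal_ml, events$toe_off) - v(signal_ml, events$heel_off),
    amp_unloading_ap = v(signal_ap, events$toe_off) - v(signal_ap, events$heel_off))
}

apa_param_names <- function() {
  c("dur_imbalance", "dur_unloading", "dur_apa", "dur_swing", "dur_step",
    "amp_imbalance_ml", "amp_imbalance_ap", "amp_unloading_ml",
    "amp_unloading_ap")
}

#' One-row trial summary of APA parameters
#'
#' @param subject Subject identifier.
#' @param task Task name.
#' @param source `"force_plate"` or `"imu"`.
#' @param events Detected `apa_events`.
#' @param signal_ml,signal_ap Filtered ML/AP signals for the amplitudes
#'   (COP for force plate, trunk acceleration for IMU).
#' @return A one-row `data.frame` with subject, task, source and the nine
#'   parameters.
#' @export
trial_summary <- function(subject, task, source, events, signal_ml, signal_ap) {
  d <- compute_durations(events)
  a <- compute_amplitudes(signal_ml, signal_ap, events)
  cbind(data.frame(subject = subject, task = task, source = source,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(c(d, a))))
}

#' Average trial summaries within subjects
#'
#' Arithmetic mean of every parameter over each subject's trials.  All
#' rows must share one task and one source (the protocol averages the
#' three repetitions of one test).
#'
#' @param summaries A `data.frame` of [trial_summary()] rows.
#' @return One row per subject.
#' @export
average_trials <- function(summaries) {
  if (!nrow(summaries)) {
    apa_error("apa_insufficient_data_error", "no trial summaries to average")
  }
  if (length(unique(summaries$task)) > 1L ||
      length(unique(summaries$source)) > 1L) {
    apa_error("apa_grouping_error",
              "trial summaries mix tasks or sources; average one test at a time")
  }
  pars <- apa_param_names()
  agg <- stats::aggregate(summaries[pars], by = list(subject = summaries$subject),
                          FUN = mean)
  cbind(data.frame(subject = agg$subject, task = summaries$task[1],
                   source = summaries$source[1], stringsAsFactors = FALSE),
        agg[pars])
}

#' Concurrent validity: wearable vs force-plate parameters
#'
#' Pearson correlation (r and p-value) per APA parameter between paired
#' per-subject summaries from the two measurement systems, mirroring a
#' linear-regression validity analysis.
#'
#' @param fp_summaries,imu_summaries Per-subject summary `data.frame`s
#'   (same task) from the force plate and the wearable system; paired by
#'   `subject`.
#' @return A `data.frame` with `parameter`, `n`, `r`, `p` and a
#'   `degenerate` flag for zero-variance pairs.
#' @export
validate_against_fp <- function(fp_summaries, imu_summaries) {
  m <- merge(fp_summaries, imu_summaries, by = "subject",
             suffixes = c("_fp", "_imu"))
  if (nrow(m) < 3L) {
    apa_error("apa_insufficient_data_error",
              sprintf("need at least 3 paired subjects, got %d", nrow(m)))
  }
  rows <- lapply(apa_param_names(), function(p) {
    x <- m[[paste0(p, "_fp")]]
    y <- m[[paste0(p, "_imu")]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(parameter = p, n = length(x), r = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(parameter = p, n = length(x), r = unname(ct$estimate),
               p = ct$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}

#' Group comparison of APA parameters
#'
#' Per-parameter Student's t-test: unpaired between two groups (e.g. PD
#' patients vs healthy controls) or paired within subjects (e.g. gait
#' initiation vs step climbing; rows are matched by `subject`).
#' Normality of the analyzed values (Shapiro-Wilk) and, for the unpaired
#' case, homoscedasticity (Bartlett) are screened and reported but never
#' switch the test family.
#'
#' @param summaries_a,summaries_b Per-subject summary `data.frame`s.
#' @param paired Paired t-test (matched by subject) instead of the
#'   two-sample test.
#' @param alpha Significance level (default 0.05).
#' @return A `data.frame` with group means and SDs, `t`, `df`, `p`,
#'   `significant`, and screening p-values `shapiro_p` / `bartlett_p`.
#' @export
compare_groups <- function(summaries_a, summaries_b, paired = FALSE,
                           alpha = 0.05) {
  if (nrow(summaries_a) < 2L || nrow(summaries_b) < 2L) {
    apa_error("apa_insufficient_data_error",
              "need at least 2 subjects per group")
  }
  if (paired) {
    m <- merge(summaries_a, summaries_b, by = "subject",
               suffixes = c("_a", "_b"))
    if (nrow(m) < 2L) {
      apa_error("apa_insufficient_data_error",
                "fewer than 2 matched subjects for the paired comparison")
    }
  }
  rows <- lapply(apa_param_names(), function(p) {
    if (paired) {
      x <- m[[paste0(p, "_a")]]
      y <- m[[paste0(p, "_b")]]
    } else {
      x <- summaries_a[[p]]
      y <- summaries_b[[p]]
    }
    d <- if (paired) x - y else NULL
    if (paired && stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(x, y, paired = paired, var.equal = !paired)
    }
    sh <- tryCatch({
      if (paired) stats::shapiro.test(d)$p.value
      else min(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
    }, error = function(e) NA_real_)
    ba <- if (paired) NA_real_ else tryCatch(
      stats::bartlett.test(list(x, y))$p.value, error = function(e) NA_real_)
    data.frame(parameter = p,
               mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, significant = tt$p.value < alpha,
               shapiro_p = sh, bartlett_p = ba)
  })
  do.call(rbind, rows)
}
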