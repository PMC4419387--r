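#' Uniformly sampled single-channel time series
#'
#' The basic signal carrier used throughout the package.  Sample `i`
#' (1-based) is taken at time `t0 + (i - 1) / fs`; event times everywhere in
#' the package are continuous seconds on this axis, so 800 Hz force-plate
#' and 50 Hz inertial streams compare directly.
#'
#' @param values Numeric vector of samples; must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds.
#' @param units Free-text unit tag (e.g. `"cm"`, `"m/s^2"`, `"deg/s"`).
#' @return An object of class `apa_ts`.
#' @export
time_series <- function(values, fs, t0 = 0, units = "") {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(t0, "t0")
  values <- as.numeric(values)
  if (length(values) == 0L) {
    apa_error("apa_schema_error", "time series must contain at least one sample")
  }
  if (!all(is.finite(values))) {
    apa_error("apa_schema_error", "time series values must all be finite")
  }
  structure(list(t0 = t0, fs = fs, values = values, units = as.character(units)),
            class = "apa_ts")
}

is_time_series <- function(x) inherits(x, "apa_ts")

#' Sample times of a time series
#' @param x An `apa_ts` object.
#' @return Numeric vector of times in seconds.
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$values) - 1) / x$fs

ts_end <- function(x) x$t0 + (length(x$values) - 1) / x$fs

#' Index of the sample nearest to a time
#' @param x An `apa_ts` object.
#' @param t Time in seconds.
#' @param check Error if `t` lies outside the record.
#' @export
ts_index <- function(x, t, check = TRUE) {
  if (check && (t < x$t0 - 0.5 / x$fs || t > ts_end(x) + 0.5 / x$fs)) {
    apa_error("apa_range_error",
              sprintf("time %.6f s lies outside the record [%.6f, %.6f]",
                      t, x$t0, ts_end(x)))
  }
  i <- as.integer(round((t - x$t0) * x$fs)) + 1L
  min(max(i, 1L), length(x$values))
}

#' Signal value at the sample nearest to a time
#' @inheritParams ts_index
#' @export
ts_at <- function(x, t, check = TRUE) x$values[ts_index(x, t, check = check)]

# Indices whose sample times fall in [from, to].
ts_window_idx <- function(x, from, to) {
  tt <- ts_times(x)
  which(tt >= from & tt <= to)
}

#' @export
print.apa_ts <- function(x, ...) {
  cat(sprintf("<apa_ts> %d samples @ %g Hz, t0 = %g s, units = '%s'\n",
              length(x$values), x$fs, x$t0, x$units))
  invisible(x)
}

# All series share fs and t0 (within tolerance); used by recording validators.
check_aligned <- function(series, what) {
  fs <- vapply(series, function(s) s$fs, numeric(1))
  t0 <- vapply(series, function(s) s$t0, numeric(1))
  n <- vapply(series, function(s) length(s$values), integer(1))
  if (diff(range(fs)) > 1e-9 || diff(range(t0)) > 1e-9 || diff(range(n)) > 0) {
    apa_error("apa_schema_error",
              sprintf("%s channels must share fs, t0 and length", what))
  }
  invisible(TRUE)
}
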