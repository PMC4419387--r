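#' Write a recording to CSV with a JSON metadata sidecar
#'
#' Signals go to `<path>` as comma-separated values, one row per sample,
#' one column per channel, full double precision (bit-exact round trip).
#' Metadata (sampling rate, t0, units, body weight, quiet window, task,
#' stepping side) goes to `<path>.json`.  Recordings with
#' `stepping_side = "left"` are stored with the raw (unmirrored) ML sign;
#' [read_recording()] re-applies the stepping-side mirror so that in-memory
#' ML is always positive toward the stepping side.
#'
#' @param rec An `apa_fp_recording` or `apa_imu_recording`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  is_fp <- inherits(rec, "apa_fp_recording")
  if (!is_fp && !inherits(rec, "apa_imu_recording")) {
    apa_error("apa_schema_error", "rec must be a force-plate or IMU recording")
  }
  chans <- recording_channels(if (is_fp) "force_plate" else "imu")
  mirror <- if (rec$stepping_side == "left") -1 else 1
  cols <- lapply(chans, function(nm) {
    v <- rec[[nm]]$values
    if (grepl("_ml$", nm)) v * mirror else v
  })
  names(cols) <- chans
  df <- as.data.frame(cols)
  ref <- rec[[chans[1]]]
  meta <- list(
    type = if (is_fp) "force_plate" else "imu",
    fs = ref$fs, t0 = ref$t0,
    units = lapply(stats::setNames(chans, chans), function(nm) rec[[nm]]$units),
    quiet_window = rec$quiet_window, task = rec$task,
    stepping_side = rec$stepping_side)
  if (is_fp) meta$body_weight <- rec$body_weight
  write_atomic(function(tmp) {
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     tmp, row.names = FALSE, quote = FALSE)
  }, path)
  write_atomic(function(tmp) {
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, paste0(path, ".json"))
  invisible(path)
}

recording_channels <- function(schema) {
  switch(schema,
         force_plate = c("cop1_ml", "cop1_ap", "fz1", "fz2"),
         imu = c("trunk_acc_v", "trunk_acc_ml", "trunk_acc_ap", "shank_gyro_ml"),
         apa_error("apa_schema_error",
                   "schema must be 'force_plate' or 'imu'"))
}

#' Read a recording written by [write_recording()]
#'
#' @param path CSV file path; `<path>.json` must exist alongside.
#' @param schema `"force_plate"` or `"imu"`; defaults to the sidecar's type.
#' @return A validated `apa_fp_recording` or `apa_imu_recording`.
#' @export
read_recording <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    apa_error("apa_io_error", sprintf("recording file not found: %s", path))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    apa_error("apa_io_error", sprintf("metadata sidecar not found: %s", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  schema <- schema %||% meta$type
  chans <- recording_channels(schema)
  df <- utils::read.csv(path, check.names = FALSE)
  for (nm in chans) {
    if (!nm %in% names(df)) {
      apa_error("apa_schema_error", sprintf("%s absent", nm), field = nm)
    }
    if (!is.numeric(df[[nm]])) {
      apa_error("apa_schema_error",
                sprintf("channel '%s' contains non-numeric cells", nm),
                field = nm)
    }
  }
  fs <- meta$fs
  if (is.null(fs) || !is.numeric(fs) || fs <= 0) {
    apa_error("apa_schema_error", "fs missing or non-positive in sidecar",
              field = "fs")
  }
  t0 <- meta$t0 %||% 0
  mirror <- if (identical(meta$stepping_side, "left")) -1 else 1
  mk <- function(nm) {
    v <- df[[nm]]
    if (grepl("_ml$", nm)) v <- v * mirror
    time_series(v, fs = fs, t0 = t0, units = meta$units[[nm]] %||% "")
  }
  qw <- as.numeric(meta$quiet_window)
  if (schema == "force_plate") {
    force_plate_recording(mk("cop1_ml"), mk("cop1_ap"), mk("fz1"), mk("fz2"),
                          body_weight = meta$body_weight,
                          quiet_window = qw, task = meta$task,
                          stepping_side = meta$stepping_side %||% "right")
  } else {
    imu_recording(mk("trunk_acc_v"), mk("trunk_acc_ml"), mk("trunk_acc_ap"),
                  mk("shank_gyro_ml"), quiet_window = qw, task = meta$task,
                  stepping_side = meta$stepping_side %||% "right")
  }
}

#' Write / read detected events as JSON
#'
#' Event times are stored as decimal seconds at full precision; reading
#' validates the event-ordering invariant and fails with an integrity
#' error if it is violated.
#'
#' @param events An `apa_events` object.
#' @param path JSON file path.
#' @export
write_events <- function(events, path) {
  if (!inherits(events, "apa_events")) {
    apa_error("apa_schema_error", "events must be an apa_events object")
  }
  doc <- events
  class(doc) <- NULL
  doc$trailing_toe_off <- if (is.finite(events$trailing_toe_off)) {
    events$trailing_toe_off
  } else NULL
  write_atomic(function(tmp) {
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    apa_error("apa_io_error", sprintf("events file not found: %s", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  gait_events(apa_onset = doc$apa_onset, heel_off = doc$heel_off,
              toe_off = doc$toe_off, foot_contact = doc$foot_contact,
              trailing_toe_off = doc$trailing_toe_off %||% NA_real_,
              source = doc$source %||% "force_plate")
}

#' Write / read threshold sets as JSON
#'
#' The file maps task names to `A`/`H`/`T` factors (plus the GRF contact
#' fraction), e.g. as produced by [calibrate()].
#'
#' @param x Named list of `apa_thresholds` (names are tasks), or a single
#'   `apa_thresholds`.
#' @param path JSON file path.
#' @export
write_thresholds <- function(x, path) {
  if (inherits(x, "apa_thresholds")) x <- list(default = x)
  doc <- lapply(x, unclass)
  write_atomic(function(tmp) {
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) {
    apa_error("apa_io_error", sprintf("thresholds file not found: %s", path))
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(doc, function(d) {
    thresholds(A = d$A, H = d$H, T_ = d$T,
               fc_grf_fraction = d$fc_grf_fraction %||% 0.065)
  })
}
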