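# Canonical cage-data CSV dialect and trace validation.
#
# gas:      subject_id,group,timepoint,timestamp,vo2,vco2
# activity: subject_id,timestamp,x_total,x_amb,y_total,y_amb,z_total
#
# Timestamps are wall-clock ISO-8601 (timezone-naive); floats are written at
# fixed 6 decimals so repeated writes are byte-identical.

gas_cols <- c("subject_id", "group", "timepoint", "timestamp", "vo2", "vco2")
activity_cols <- c("subject_id", "timestamp", "x_total", "x_amb",
                   "y_total", "y_amb", "z_total")

#' The light/dark phase schedule
#'
#' @param light_on,light_off Clock times ("HH:MM") when the light phase starts
#'   and ends; must partition the day into two 12-h blocks.
#' @return A `phase_schedule` list with minutes-of-day fields.
#' @export
#' @examples
#' phase_schedule()
phase_schedule <- function(light_on = "06:00", light_off = "18:00") {
  on <- parse_clock(light_on); off <- parse_clock(light_off)
  if ((off - on) %% 1440 != 720) {
    abort("phases must partition 24 h into two 12-h blocks")
  }
  structure(list(light_on = on, light_off = off), class = "phase_schedule")
}

validate_calorimetry_trace <- function(tr) {
  missing <- setdiff(gas_cols, names(tr))
  if (length(missing)) {
    abort(paste("gas trace missing columns:", paste(missing, collapse = ", ")))
  }
  width <- attr(tr, "interval_width") %||% 4
  bad <- which(!(tr$vo2 > 0 & tr$vco2 > 0))
  if (length(bad)) {
    abort(paste0("non-positive gas values at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (nrow(tr) > 1) {
    dt <- as.numeric(diff(tr$timestamp), units = "mins")
    bad <- which(abs(dt - width) > 1e-6)
    if (length(bad)) {
      abort(paste0("timestamps not uniformly increasing at ", width,
                   "-min spacing; first offending row ", bad[1] + 1))
    }
  }
  if (!inherits(tr, "calorimetry_trace")) {
    class(tr) <- c("calorimetry_trace", class(tr))
  }
  attr(tr, "interval_width") <- width
  tr
}

validate_activity_trace <- function(tr) {
  missing <- setdiff(activity_cols, names(tr))
  if (length(missing)) {
    abort(paste("activity trace missing columns:",
                paste(missing, collapse = ", ")))
  }
  counts <- as.matrix(tr[c("x_total", "x_amb", "y_total", "y_amb", "z_total")])
  bad <- which(rowSums(counts < 0 | counts != floor(counts)) > 0)
  if (length(bad)) {
    abort(paste0("negative or non-integer counts at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- which(tr$x_amb > tr$x_total | tr$y_amb > tr$y_total)
  if (length(bad)) {
    abort(paste0("ambulatory exceeds total counts at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (nrow(tr) > 1) {
    dt <- as.numeric(diff(tr$timestamp), units = "secs")
    bad <- which(abs(dt - 10) > 1e-6)
    if (length(bad)) {
      abort(paste0("timestamps not uniformly increasing at 10-s spacing; ",
                   "first offending row ", bad[1] + 1))
    }
  }
  if (!inherits(tr, "activity_trace")) {
    class(tr) <- c("activity_trace", class(tr))
  }
  tr
}

#' Read a cage-data CSV in the canonical dialect
#'
#' @param path File path.
#' @param kind `"gas"` (4-min VO2/VCO2 intervals) or `"activity"` (10-s
#'   beam-break bins).
#' @return A validated `calorimetry_trace` or `activity_trace` tibble.
#' @export
read_trace_csv <- function(path, kind = c("gas", "activity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste("no such file:", path))
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expected <- if (kind == "gas") gas_cols else activity_cols
  if (!identical(header, expected)) {
    abort(paste0(kind, " file header must be: ",
                 paste(expected, collapse = ",")))
  }
  if (kind == "gas") {
    tr <- readr::read_csv(
      path,
      col_types = readr::cols(
        subject_id = "c", group = "c", timepoint = "c",
        timestamp = readr::col_datetime("%Y-%m-%dT%H:%M:%S"),
        vo2 = "d", vco2 = "d"
      )
    )
    if (!identical(names(tr), gas_cols)) {
      abort(paste("gas file header must be:", paste(gas_cols, collapse = ",")))
    }
    validate_calorimetry_trace(tr)
  } else {
    tr <- readr::read_csv(
      path,
      col_types = readr::cols(
        subject_id = "c",
        timestamp = readr::col_datetime("%Y-%m-%dT%H:%M:%S"),
        x_total = "i", x_amb = "i", y_total = "i", y_amb = "i", z_total = "i"
      )
    )
    if (!identical(names(tr), activity_cols)) {
      abort(paste("activity file header must be:",
                  paste(activity_cols, collapse = ",")))
    }
    validate_activity_trace(tr)
  }
}

#' Write a trace in the canonical CSV dialect
#'
#' Canonical column order, ISO-8601 timestamps, fixed 6-decimal floats:
#' writing the same trace twice produces identical bytes, and a written file
#' re-read and re-written is byte-stable.
#'
#' @param trace A `calorimetry_trace` or `activity_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (inherits(trace, "calorimetry_trace") || all(gas_cols %in% names(trace))) {
    trace <- validate_calorimetry_trace(trace)
    lines <- c(
      paste(gas_cols, collapse = ","),
      if (nrow(trace)) {
        sprintf("%s,%s,%s,%s,%.6f,%.6f",
                trace$subject_id, trace$group, trace$timepoint,
                iso(trace$timestamp), trace$vo2, trace$vco2)
      }
    )
  } else if (inherits(trace, "activity_trace") ||
             all(activity_cols %in% names(trace))) {
    trace <- validate_activity_trace(trace)
    lines <- c(
      paste(activity_cols, collapse = ","),
      if (nrow(trace)) {
        sprintf("%s,%s,%d,%d,%d,%d,%d",
                trace$subject_id, iso(trace$timestamp),
                trace$x_total, trace$x_amb, trace$y_total, trace$y_amb,
                trace$z_total)
      }
    )
  } else {
    abort("not a recognizable trace")
  }
  writeLines(lines, path)
  invisible(path)
}
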