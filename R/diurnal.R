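# Diurnal analysis: phase assignment, multi-resolution binning, hourly moving
# averages, trapezoidal AUC, and the phase-delta flexibility metrics.

# hours since the start of the subject-day (a day runs light-on -> light-on,
# i.e. 06:00 -> 06:00, so each day holds one full inactive then active phase)
hours_since_day_start <- function(time, schedule = phase_schedule()) {
  (clock_minutes(time) - schedule$light_on) %% 1440 / 60
}

#' Assign light/dark phase to timestamps
#'
#' Clock times in `[light_on, light_off)` are the light (inactive) phase; all
#' others are the dark (active) phase. The half-open convention puts the
#' boundary instants 06:00 and 18:00 into the phase that begins there.
#'
#' @param time POSIXct timestamps, or clock strings ("HH:MM").
#' @param schedule A [phase_schedule()].
#' @return Character vector, `"active"` or `"inactive"`.
#' @export
#' @examples
#' assign_phase(c("10:00", "20:00", "06:00"))
assign_phase <- function(time, schedule = phase_schedule()) {
  mins <- if (inherits(time, "POSIXt")) clock_minutes(time)
          else vapply(time, parse_clock, numeric(1), USE.NAMES = FALSE)
  rel <- (mins - schedule$light_on) %% 1440
  ifelse(rel < (schedule$light_off - schedule$light_on) %% 1440,
         "inactive", "active")
}

series_channels <- function(series) {
  setdiff(names(series)[vapply(series, is.numeric, logical(1))],
          c("timestamp"))
}

check_full_day <- function(series, width_min) {
  expected <- 1440 / width_min
  if (nrow(series) != expected) {
    abort(paste0("series must span exactly 24 h (", expected, " intervals at ",
                 width_min, " min); got ", nrow(series)))
  }
}

#' Bin a 24-h metabolic series
#'
#' Arithmetic mean and SD of every numeric channel over consecutive clock
#' bins. Bins are anchored at the day start (light-on, 06:00), so 6-h bins
#' start at 06:00, 12:00, 18:00 and 00:00, and 12-h bins are exactly the
#' inactive and active phases.
#'
#' @param series A `metabolic_series` (or any tibble with `timestamp` plus
#'   numeric channels) spanning exactly 24 h.
#' @param bin_width Bin width in hours; must divide 24 (the study uses
#'   1, 6, 12 and 24).
#' @param schedule A [phase_schedule()].
#' @return Tibble, one row per bin x channel: `bin_width`, `bin_start`
#'   (clock "HH:MM"), `phase` (`active`/`inactive`/`mixed`), `channel`,
#'   `mean`, `sd`, `n`.
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' bin_series(derive_metabolic_series(tr), 12)
bin_series <- function(series, bin_width, schedule = phase_schedule()) {
  if (24 %% bin_width != 0) abort("bin_width must divide 24")
  width_min <- attr(series, "interval_width") %||% 4
  check_full_day(series, width_min)
  h <- hours_since_day_start(series$timestamp, schedule)
  bin <- floor(h / bin_width)
  chans <- series_channels(series)
  series |>
    dplyr::mutate(.bin = bin) |>
    tidyr::pivot_longer(dplyr::all_of(chans), names_to = "channel",
                        values_to = "value") |>
    dplyr::group_by(.data$.bin, .data$channel) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      start_min = (schedule$light_on + .data$.bin * .env$bin_width * 60) %% 1440,
      bin_start = sprintf("%02d:%02d", .data$start_min %/% 60,
                          .data$start_min %% 60),
      phase = if (.env$bin_width > 12) "mixed"
              else assign_phase(.data$bin_start, schedule),
      bin_width = .env$bin_width
    ) |>
    dplyr::select("bin_width", "bin_start", "phase", "channel",
                  "mean", "sd", "n") |>
    dplyr::arrange(.data$channel)
}

#' Trailing hourly moving average of a metabolic series
#'
#' Smooths every numeric channel with a trailing window of `window`
#' consecutive intervals (15 four-minute intervals = one hour). The output
#' has `nrow(series) - window + 1` rows and each smoothed point carries the
#' timestamp of the last interval in its window.
#'
#' @param series Series tibble with `timestamp` and numeric channels.
#' @param window Window length in intervals.
#' @return Smoothed series tibble (same channel columns).
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' nrow(moving_average(derive_metabolic_series(tr)))
moving_average <- function(series, window = 15) {
  n <- nrow(series)
  if (n < window) abort(paste0("series length ", n, " < window ", window))
  chans <- series_channels(series)
  keep <- window:n
  smoothed <- lapply(series[chans], function(x) {
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))[keep]
  })
  out <- dplyr::bind_cols(
    dplyr::select(as_tibble(series),
                  dplyr::any_of(c("subject_id", "group", "timepoint")))[keep, ],
    tibble(timestamp = series$timestamp[keep]),
    as_tibble(smoothed)
  )
  attr(out, "interval_width") <- attr(series, "interval_width") %||% 4
  attr(out, "window") <- window
  out
}

#' Trapezoidal area under a smoothed diurnal curve
#'
#' The x axis is time in hours (4-min spacing = 1/15 h). With `by_bin`, the
#' AUC is also computed over the points falling within each 6-h clock bin.
#'
#' @param series Smoothed series (see [moving_average()]); at least 2 points.
#' @param channel Channel name to integrate.
#' @param by_bin If `TRUE`, additionally return per-6-h-bin AUCs.
#' @param schedule A [phase_schedule()].
#' @return A single number, or (with `by_bin`) a tibble with the 24-h AUC and
#'   one row per 6-h bin.
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' auc(moving_average(derive_metabolic_series(tr)), "ee")
auc <- function(series, channel, by_bin = FALSE,
                schedule = phase_schedule()) {
  if (nrow(series) < 2) abort("AUC needs at least 2 points")
  h <- hours_since_day_start(series$timestamp, schedule)
  # the smoothed day is contiguous in time even though clock hours wrap
  x <- cumsum(c(0, diff(clock_minutes(series$timestamp)) %% 1440)) / 60
  y <- series[[channel]]
  total <- pracma::trapz(x, y)
  if (!by_bin) return(total)
  bins <- floor(h / 6)
  per_bin <- vapply(sort(unique(bins)), function(b) {
    i <- which(bins == b)
    if (length(i) < 2) return(NA_real_)
    pracma::trapz(x[i], y[i])
  }, numeric(1))
  start_min <- (schedule$light_on + sort(unique(bins)) * 360) %% 1440
  dplyr::bind_rows(
    tibble(bin_start = "24h", auc = total),
    tibble(bin_start = sprintf("%02d:%02d", start_min %/% 60,
                               start_min %% 60),
           auc = per_bin)
  )
}

#' Phase-delta and AUC metabolic-flexibility metrics for one subject-day
#'
#' Metabolic rate flux is the difference between the 12-h active and inactive
#' mean energy expenditure; metabolic flexibility is the same delta for RER.
#' AUCs of the hourly moving-average curves (24-h and per 6-h bin) give the
#' cumulative counterparts.
#'
#' @param series A full-day `metabolic_series`.
#' @param schedule A [phase_schedule()].
#' @param window Moving-average window (intervals).
#' @return One-row tibble: identity columns, `delta_ee`, `delta_rer`,
#'   `auc_ee_24h`, `auc_rer_24h`, and a list-column `auc_6h` of per-bin AUCs.
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' flexibility_metrics(derive_metabolic_series(tr))
flexibility_metrics <- function(series, schedule = phase_schedule(),
                                window = 15) {
  b12 <- bin_series(series, 12, schedule)
  delta_of <- function(chan) {
    x <- b12[b12$channel == chan, ]
    x$mean[x$phase == "active"] - x$mean[x$phase == "inactive"]
  }
  sm <- moving_average(series, window)
  auc_ee <- auc(sm, "ee", by_bin = TRUE, schedule = schedule)
  auc_rer <- auc(sm, "rer", by_bin = TRUE, schedule = schedule)
  ids <- dplyr::slice(
    dplyr::select(as_tibble(series),
                  dplyr::any_of(c("subject_id", "group", "timepoint"))), 1)
  dplyr::bind_cols(
    ids,
    tibble(
      delta_ee = delta_of("ee"),
      delta_rer = delta_of("rer"),
      auc_ee_24h = auc_ee$auc[auc_ee$bin_start == "24h"],
      auc_rer_24h = auc_rer$auc[auc_rer$bin_start == "24h"],
      auc_6h = list(tibble(
        bin_start = auc_ee$bin_start[auc_ee$bin_start != "24h"],
        auc_ee = auc_ee$auc[auc_ee$bin_start != "24h"],
        auc_rer = auc_rer$auc[auc_rer$bin_start != "24h"]
      ))
    )
  )
}
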