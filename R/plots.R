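# Diagnostic figures.

#' Diurnal profile of a metabolic channel
#'
#' Hourly moving average of one channel over the subject-day, with the dark
#' (active) phase shaded.
#'
#' @param series A `metabolic_series`.
#' @param channel Channel to plot (`"ee"`, `"rer"`, `"carb_ox"`,
#'   `"lipid_ox"`).
#' @param window Moving-average window, intervals.
#' @param schedule A [phase_schedule()].
#' @return A ggplot object.
#' @export
plot_diurnal_profile <- function(series, channel = "ee", window = 15,
                                 schedule = phase_schedule()) {
  sm <- moving_average(series, window)
  h0 <- hours_since_day_start(sm$timestamp[1], schedule)
  d <- tibble(
    hours = h0 + cumsum(c(0, diff(clock_minutes(sm$timestamp)) %% 1440)) / 60,
    value = sm[[channel]]
  )
  dark_start <- ((schedule$light_off - schedule$light_on) %% 1440) / 60
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hours, y = .data$value)) +
    ggplot2::annotate("rect", xmin = dark_start, xmax = dark_start + 12,
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "hours since light-on",
      y = switch(channel, ee = "energy expenditure (kcal/kg/hr)",
                 rer = "RER", channel),
      title = paste0(series$subject_id[1], " - hourly moving average")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_diurnal_profile
#' @param object,... Passed to [plot_diurnal_profile()].
#' @export
autoplot.metabolic_series <- function(object, ...) {
  plot_diurnal_profile(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Force-frequency curves from a muscle-function table
#'
#' @param muscle_function Table from [generate_terminal_tables()] (wide
#'   `torque_<f>hz` columns).
#' @return A ggplot object: group-mean torque against stimulation frequency.
#' @export
plot_force_frequency <- function(muscle_function) {
  d <- muscle_function |>
    tidyr::pivot_longer(dplyr::starts_with("torque_"),
                        names_to = "frequency", values_to = "torque") |>
    dplyr::mutate(frequency = as.numeric(gsub("torque_|hz", "",
                                              .data$frequency))) |>
    dplyr::group_by(.data$group, .data$frequency) |>
    dplyr::summarise(torque = mean(.data$torque), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$torque,
                                  color = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulation frequency (Hz)", y = "torque (mN·m)") +
    ggplot2::theme_minimal()
}
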