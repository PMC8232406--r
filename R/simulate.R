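# Seedable synthetic cage recordings: diurnal square waves with logistic
# light-transition ramps, AR(1) noise, Poisson beam-break activity, and
# terminal muscle-outcome tables drawn around published group means.

# latent "activeness" in [0,1] as a function of minutes since midnight:
# ~1 in the dark phase (18:00-06:00), ~0 in the light phase, logistic ramps
# of total width `transition_minutes` at both boundaries
activeness_wave <- function(min_of_day, light_on = 360, light_off = 1080,
                            transition_minutes = 60) {
  if (transition_minutes <= 0) {
    return(as.numeric(min_of_day < light_on | min_of_day >= light_off))
  }
  k <- transition_minutes / 6  # +/-3k covers ~95% of the transition
  plogis((min_of_day - light_off) / k) + plogis((light_on - min_of_day) / k)
}

# AR(1) noise with stationary sd `sigma` and lag-1 autocorrelation `phi`
ar1_noise <- function(n, sigma, phi) {
  if (sigma == 0 || n == 0) return(numeric(n))
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- sigma * z[1]
  if (n > 1) {
    innov <- sigma * sqrt(1 - phi^2)
    for (t in 2:n) e[t] <- phi * e[t - 1] + innov * z[t]
  }
  e
}

# rescale a waveform affinely so its two 12-h phase means hit the preset
# targets exactly (the logistic ramps otherwise shave a small symmetric edge
# off the phase delta)
calibrate_phases <- function(wave, phase, target_active, target_inactive) {
  a_bar <- mean(wave[phase == "active"])
  i_bar <- mean(wave[phase == "inactive"])
  if (abs(a_bar - i_bar) < .Machine$double.eps) {
    # flat wave (zero-width phases can't occur on a full day)
    return(rep((target_active + target_inactive) / 2, length(wave)))
  }
  beta <- (target_active - target_inactive) / (a_bar - i_bar)
  alpha <- target_inactive - beta * i_bar
  alpha + beta * wave
}

#' Generate one synthetic subject-day of calorimetry gas data
#'
#' Emits 360 four-minute intervals covering 24 h. Latent energy expenditure
#' and RER follow phase-level square waves with logistic ramps at the 06:00
#' and 18:00 light transitions, affinely calibrated so the noiseless 12-h
#' phase means equal the preset targets exactly, plus stationary AR(1)
#' Gaussian noise. Gas channels are then back-computed as
#' `VO2 = EE / (3.815 + 1.232 RER)` (L/kg/hr, stored as ml/kg/hr) and
#' `VCO2 = RER * VO2`, so the metric pipeline recovers the latent channels
#' identically.
#'
#' RER values driven outside `(0, 1.2]` by noise are pulled back into the
#' physiologic range `[0.7, 1.0]`; the number of such repairs is recorded in
#' the `n_rer_clamped` attribute.
#'
#' @param preset A [generator_preset()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @param subject_id,group,timepoint Labels stored on the trace.
#' @param start_clock Clock time of the first interval ("06:00": one full
#'   inactive then active phase per day).
#' @return A `calorimetry_trace` tibble with columns `subject_id`, `group`,
#'   `timepoint`, `timestamp`, `vo2`, `vco2` and attributes `interval_width`
#'   (minutes) and the latent channels `latent_ee`, `latent_rer`.
#' @export
#' @examples
#' tr <- generate_calorimetry_trace(builtin_presets()$baseline, seed = 1)
#' nrow(tr)
generate_calorimetry_trace <- function(preset, seed,
                                       subject_id = "S1",
                                       group = preset$name,
                                       timepoint = "pre",
                                       start_clock = "06:00") {
  validate_preset(preset)
  width <- 4L
  n <- 1440L %/% width  # 360 intervals over the 24-h horizon
  t0 <- .metaflex_epoch(start_clock)
  ts <- t0 + (seq_len(n) - 1L) * width * 60
  mins <- clock_minutes(ts)
  phase <- assign_phase(ts)

  wave <- activeness_wave(mins, transition_minutes = preset$transition_minutes)
  ee_lat <- calibrate_phases(wave, phase, preset$ee_active_mean,
                             preset$ee_inactive_mean)
  rer_lat <- calibrate_phases(wave, phase, preset$rer_active_mean,
                              preset$rer_inactive_mean)

  withr::with_seed(seed, {
    ee <- ee_lat + ar1_noise(n, preset$ee_noise_sd, preset$ar_coefficient)
    rer <- rer_lat + ar1_noise(n, preset$rer_noise_sd, preset$ar_coefficient)
  })
  ee <- pmax(ee, 1e-6)
  out_of_range <- rer <= 0 | rer > 1.2
  rer[out_of_range] <- pmin(pmax(rer[out_of_range], 0.7), 1.0)

  vo2 <- 1000 * ee / (3.815 + 1.232 * rer)  # ml/kg/hr
  vco2 <- rer * vo2

  tr <- tibble(
    subject_id = subject_id, group = group, timepoint = timepoint,
    timestamp = ts, vo2 = vo2, vco2 = vco2
  )
  attr(tr, "interval_width") <- width
  attr(tr, "latent_ee") <- ee
  attr(tr, "latent_rer") <- rer
  attr(tr, "n_rer_clamped") <- sum(out_of_range)
  class(tr) <- c("calorimetry_trace", class(tibble()))
  tr
}

#' Generate one synthetic subject-day of beam-break activity data
#'
#' Emits 8,640 ten-second bins. Ambulatory counts per bin are Poisson with a
#' phase-specific rate split evenly across the X and Y axes; non-ambulatory
#' counts (in-place movement) add a further Poisson component at
#' `nonamb_fraction` of the ambulatory rate, and Z-axis (rearing) totals use
#' the same fraction. Under the baseline preset the expected 24-h ambulation
#' distance at 1.27 cm per count is exactly 1.3 km, 1.0 km of it in the dark
#' phase.
#'
#' @inheritParams generate_calorimetry_trace
#' @return An `activity_trace` tibble with columns `subject_id`, `timestamp`,
#'   `x_total`, `x_amb`, `y_total`, `y_amb`, `z_total`.
#' @export
#' @examples
#' at <- generate_activity_trace(builtin_presets()$baseline, seed = 1)
#' nrow(at)
generate_activity_trace <- function(preset, seed, subject_id = "S1",
                                    start_clock = "06:00") {
  validate_preset(preset)
  n <- 8640L
  t0 <- .metaflex_epoch(start_clock)
  ts <- t0 + (seq_len(n) - 1L) * 10
  phase <- assign_phase(ts)
  rate <- ifelse(phase == "active", preset$amb_rate_active,
                 preset$amb_rate_inactive)
  axis_rate <- rate / 2

  withr::with_seed(seed, {
    x_amb <- rpois(n, axis_rate)
    y_amb <- rpois(n, axis_rate)
    x_non <- rpois(n, preset$nonamb_fraction * axis_rate)
    y_non <- rpois(n, preset$nonamb_fraction * axis_rate)
    z_tot <- rpois(n, preset$nonamb_fraction * axis_rate)
  })

  tr <- tibble(
    subject_id = subject_id, timestamp = ts,
    x_total = x_amb + x_non, x_amb = x_amb,
    y_total = y_amb + y_non, y_amb = y_amb,
    z_total = z_tot
  )
  class(tr) <- c("activity_trace", class(tibble()))
  tr
}

# deterministic, documented seed-derivation scheme: a Lehmer-style mix of the
# design seed with subject, timepoint and stream indices, kept within 32-bit
# integer range (all intermediates stay below 2^53 so double arithmetic is
# exact)
derive_seed <- function(seed, subject_idx, timepoint_idx, stream = 1L) {
  m <- 2147483647
  x <- (seed %% m) * 48271 + subject_idx * 9949 +
    timepoint_idx * 211 + stream * 7907
  as.integer(x %% m) + 1L
}

#' Describe a synthetic cohort
#'
#' @param groups Named integer vector: subjects per group,
#'   e.g. `c(baseline = 28)`.
#' @param timepoints Character vector of timepoint labels.
#' @param presets Tibble with columns `group`, `timepoint`, `preset`
#'   (list-column of [generator_preset()]); every (group, timepoint) pair must
#'   appear exactly once. Defaults to the single built-in preset named by the
#'   group when `NULL` and all groups match built-in preset names.
#' @param seed Integer master seed.
#' @return A `cohort_design` list.
#' @export
#' @examples
#' cohort_design(c(baseline = 4), "pre", seed = 1)
cohort_design <- function(groups, timepoints = "pre", presets = NULL,
                          seed = 1L) {
  if (is.null(names(groups)) || any(groups < 1)) {
    abort("groups must be a named vector of subject counts >= 1")
  }
  if (is.null(presets)) {
    reg <- builtin_presets()
    if (!all(names(groups) %in% names(reg))) {
      abort("no preset table given and group names are not built-in presets")
    }
    presets <- tidyr::expand_grid(group = names(groups),
                                  timepoint = timepoints) |>
      dplyr::mutate(preset = purrr::map(.data$group, ~reg[[.x]]))
  }
  key <- paste(presets$group, presets$timepoint)
  need <- paste(rep(names(groups), each = length(timepoints)),
                rep(timepoints, times = length(groups)))
  if (anyDuplicated(key) || !all(need %in% key)) {
    abort("presets must map each (group, timepoint) to exactly one preset")
  }
  structure(list(groups = groups, timepoints = timepoints,
                 presets = presets, seed = as.integer(seed)),
            class = "cohort_design")
}

#' The longitudinal VML study design
#'
#' Twelve subjects recorded at three timepoints (`pre`, `2wk`, `6wk`) under
#' the `baseline`, `vml_2wk` and `vml_6wk` presets; subjects persist across
#' timepoints (repeated-measures structure).
#'
#' @param n Subjects.
#' @param seed Master seed.
#' @return A [cohort_design()].
#' @export
longitudinal_vml_design <- function(n = 12, seed = 1L) {
  reg <- builtin_presets()
  presets <- tibble(
    group = "vml", timepoint = c("pre", "2wk", "6wk"),
    preset = list(reg$baseline, reg$vml_2wk, reg$vml_6wk)
  )
  cohort_design(c(vml = n), c("pre", "2wk", "6wk"), presets, seed)
}

#' Generate a full synthetic cohort of cage recordings
#'
#' One calorimetry and/or activity trace per subject per timepoint. Trace
#' seeds are derived deterministically from the design seed and the subject
#' and timepoint indices, so identical designs reproduce identical cohorts
#' and subjects keep their identity across timepoints.
#'
#' @param design A [cohort_design()].
#' @param what Which trace kinds to generate.
#' @return Tibble with one row per subject x timepoint: `subject_id`, `group`,
#'   `timepoint`, and list-columns `calorimetry` and/or `activity`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_design(c(baseline = 2), seed = 7))
#' nrow(coh)
generate_cohort <- function(design,
                            what = c("both", "calorimetry", "activity")) {
  stopifnot(inherits(design, "cohort_design"))
  what <- match.arg(what)
  subjects <- tibble(
    group = rep(names(design$groups), times = design$groups),
    subject_id = paste0(rep(names(design$groups), times = design$groups), "_",
                        unlist(lapply(design$groups, seq_len)))
  )
  if (anyDuplicated(subjects$subject_id)) abort("duplicate subject labels")
  subjects$subject_idx <- seq_len(nrow(subjects))

  grid <- tidyr::expand_grid(subjects,
                             timepoint = design$timepoints) |>
    dplyr::mutate(timepoint_idx = match(.data$timepoint, design$timepoints)) |>
    dplyr::left_join(design$presets, by = c("group", "timepoint"))

  if (what %in% c("both", "calorimetry")) {
    grid$calorimetry <- purrr::pmap(
      list(grid$preset, grid$subject_idx, grid$timepoint_idx,
           grid$subject_id, grid$group, grid$timepoint),
      function(p, si, ti, id, g, tp) {
        generate_calorimetry_trace(
          p, seed = derive_seed(design$seed, si, ti, 1L),
          subject_id = id, group = g, timepoint = tp
        )
      }
    )
  }
  if (what %in% c("both", "activity")) {
    grid$activity <- purrr::pmap(
      list(grid$preset, grid$subject_idx, grid$timepoint_idx, grid$subject_id),
      function(p, si, ti, id) {
        generate_activity_trace(p, seed = derive_seed(design$seed, si, ti, 2L),
                                subject_id = id)
      }
    )
  }
  dplyr::select(grid, "subject_id", "group", "timepoint",
                dplyr::any_of(c("calorimetry", "activity")))
}
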