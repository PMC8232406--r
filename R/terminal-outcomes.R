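# Terminal muscle-function and histomorphometry metrics.

#' Percent change relative to a reference
#'
#' @param reference Reference value (nonzero).
#' @param observed Observed value.
#' @return `100 * (observed - reference) / reference`.
#' @export
#' @examples
#' percent_change(1.08, 0.84)   # ~ -22% gastrocnemius weight-ratio reduction
percent_change <- function(reference, observed) {
  if (any(reference == 0)) abort("reference must be nonzero")
  100 * (observed - reference) / reference
}

#' Twitch-to-tetanus torque ratio
#'
#' Peak single-twitch torque divided by peak tetanic torque, an index of
#' excitation-contraction properties.
#'
#' @param peak_twitch,peak_torque Torques, mN.m; `peak_torque` must be > 0.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' twitch_tetani_ratio(4.1, 19.2)
twitch_tetani_ratio <- function(peak_twitch, peak_torque) {
  if (any(peak_torque <= 0)) abort("peak_torque must be > 0")
  peak_twitch / peak_torque
}

#' Torque normalized to body mass
#'
#' @param torque mN.m.
#' @param body_mass Grams (> 0).
#' @return mN.m per kg body mass.
#' @export
#' @examples
#' normalize_torque(19.2, 30.5)
normalize_torque <- function(torque, body_mass) {
  if (any(body_mass <= 0)) abort("body_mass must be > 0")
  torque / (body_mass / 1000)
}

#' Filter fiber records by cross-sectional area
#'
#' Keeps fibers with CSA in the inclusive range `[lower, upper]`
#' (50-7,500 um^2 by default, the quantification window for fiber CSA).
#'
#' @param records Fiber tibble with a `csa` column.
#' @param lower,upper Bounds, um^2 (inclusive).
#' @return Filtered tibble.
#' @export
#' @examples
#' filter_fibers_by_csa(tibble::tibble(csa = c(40, 300, 8000)))
filter_fibers_by_csa <- function(records, lower = 50, upper = 7500) {
  dplyr::filter(records, .data$csa >= lower, .data$csa <= upper)
}

#' Summarize fiber-level histology records
#'
#' Per-region or whole-muscle pooled summaries of fiber-type composition,
#' type-specific CSA, central-nucleation, oxidative staining, and
#' capillarity. Whole-muscle pooling sums fiber counts across the three
#' regions of interest (proportions recomputed from pooled counts; CSA pooled
#' at the fiber level); subjects missing any of the three regions are
#' excluded from the whole-muscle table but remain in regional summaries.
#'
#' @param records Fiber tibble: `subject_id`, `region`
#'   (`lateral`/`mid`/`medial`), `fiber_type` (`I`/`IIa`/`IIb`/`IIx`), `csa`,
#'   `capillaries`, `central_nucleus`, `nadh_positive`, `sdh_positive`
#'   (optionally `group`).
#' @param pooling `"per-region"` or `"whole-muscle"`.
#' @return List of tibbles: `composition` (per grouping x fiber type: count,
#'   proportion, mean CSA), `summary` (per grouping: n fibers, % central
#'   nuclei, % NADH+, % SDH+, mean capillaries per fiber), and
#'   `capillary_hist` (per grouping: capillaries-per-fiber histogram).
#' @export
#' @examples
#' tt <- generate_terminal_tables(n_control = 2, n_vml4 = 1, n_vml8 = 1,
#'                                seed = 1, fibers_per_roi = 20)
#' summarize_histology(tt$fibers, "whole-muscle")$composition
summarize_histology <- function(records,
                                pooling = c("per-region", "whole-muscle")) {
  pooling <- match.arg(pooling)
  regions <- c("lateral", "mid", "medial")
  bad <- setdiff(unique(records$region), regions)
  if (length(bad)) {
    abort(paste("unknown region label:", paste(bad, collapse = ", ")))
  }
  if (pooling == "whole-muscle") {
    complete <- records |>
      dplyr::distinct(.data$subject_id, .data$region) |>
      dplyr::count(.data$subject_id) |>
      dplyr::filter(.data$n == length(regions)) |>
      dplyr::pull(.data$subject_id)
    records <- records |>
      dplyr::filter(.data$subject_id %in% complete) |>
      dplyr::mutate(region = "whole")
  }
  keys <- intersect(c("group", "subject_id", "region"), names(records))
  grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(keys)))

  composition <- grouped |>
    dplyr::group_by(.data$fiber_type, .add = TRUE) |>
    dplyr::summarise(n_fibers = dplyr::n(), mean_csa = mean(.data$csa),
                     .groups = "drop_last") |>
    dplyr::mutate(proportion = .data$n_fibers / sum(.data$n_fibers)) |>
    dplyr::ungroup()

  summary <- grouped |>
    dplyr::summarise(
      n_fibers = dplyr::n(),
      pct_central_nuclei = 100 * mean(.data$central_nucleus),
      pct_nadh_positive = 100 * mean(.data$nadh_positive),
      pct_sdh_positive = 100 * mean(.data$sdh_positive),
      capillaries_per_fiber = mean(.data$capillaries),
      .groups = "drop"
    )

  capillary_hist <- grouped |>
    dplyr::count(.data$capillaries, name = "n_fibers") |>
    dplyr::ungroup()

  list(composition = composition, summary = summary,
       capillary_hist = capillary_hist)
}
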