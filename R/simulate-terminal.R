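# Synthetic terminal-outcome tables: per-subject muscle-function draws and
# per-fiber histology records, calibrated to the published group means/SDs
# (control n=16, VML 4-week n=5, VML 8-week n=7).

terminal_groups <- c("control", "vml_4wk", "vml_8wk")

# contractile / mass outcomes: mean and SD per group
muscle_function_calibration <- function() {
  tibble(
    group = rep(terminal_groups, each = 5),
    measure = rep(c("body_mass", "gastroc_weight_ratio", "passive_torque",
                    "peak_twitch", "peak_torque"), times = 3),
    mean = c(30.5, 1.08, 2.4, 4.1, 19.2,
             29.3, 0.84, 4.2, 2.9, 12.3,
             31.1, 0.92, 5.1, 1.9, 9.9),
    sd = c(0.6, 0.08, 0.5, 0.9, 2.5,
           1.1, 0.07, 1.4, 0.7, 1.2,
           0.9, 0.15, 1.4, 1.0, 2.4)
  )
}

# regional histology: percent central nuclei, mean capillaries per fiber,
# percent NADH-positive, percent SDH-positive
histology_calibration <- function() {
  regions <- c("lateral", "mid", "medial")
  tibble(
    region = rep(regions, each = 3),
    group = rep(terminal_groups, times = 3),
    pct_central_nuclei = c(7.2, 20.2, 33.1,  1.6, 28.1, 18.7,  8.2, 21.8, 29.7),
    capillaries_per_fiber = c(5.6, 4.4, 4.8,  3.6, 2.7, 3.9,  4.6, 5.3, 5.2),
    pct_nadh_positive = c(75.1, 87.2, 85.0,  63.0, 78.7, 72.8,  71.5, 91.3, 59.6),
    pct_sdh_positive = c(53.7, 72.5, 67.7,  30.6, 34.0, 25.8,  58.0, 66.4, 58.0)
  )
}

# fiber-type-specific mean CSA (um^2) and fiber-type percentages,
# by region x group
fiber_calibration <- function() {
  regions <- c("lateral", "mid", "medial")
  types <- c("I", "IIa", "IIb", "IIx")
  grid <- tidyr::expand_grid(region = regions, group = terminal_groups,
                             fiber_type = types)
  # CSA means, ordered region (lat, mid, med) x group (ctl, 4wk, 8wk) x type
  csa <- c(
    1333.5, 1416.9, 3026.7, 2211.7,  1232.6, 1278.0, 2218.1, 1906.3,
    1454.0, 1530.7, 2467.6, 1771.9,
    1099.1, 1289.0, 2977.7, 1777.9,  680.6, 1138.4, 1792.7, 1268.7,
    1009.5, 1563.3, 2595.0, 1976.9,
    834.7, 1241.6, 2746.3, 1597.4,   846.1, 1104.1, 2393.5, 1641.4,
    1150.0, 1165.6, 2128.7, 1791.3
  )
  pct <- c(
    3.9, 20.4, 60.4, 15.2,   9.1, 37.7, 35.8, 17.4,   15.8, 32.6, 36.9, 14.7,
    7.2, 19.2, 59.7, 13.9,   15.7, 22.8, 54.7, 6.8,    6.1, 26.5, 50.0, 17.4,
    3.9, 20.6, 59.0, 16.6,   19.1, 39.5, 22.8, 18.6,   13.4, 22.9, 50.7, 13.0
  )
  grid$mean_csa <- csa
  grid$pct_type <- pct
  grid
}

# deterministic integer allocation of n items to proportions (largest
# remainder), used when sd_scale = 0
allocate_counts <- function(n, prop) {
  prop <- prop / sum(prop)
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate synthetic terminal muscle-outcome tables
#'
#' Draws per-subject muscle-function outcomes (Gaussian around the group
#' means/SDs of the contractile-properties table) and per-fiber histology
#' records: fiber types sampled from the region- and group-specific
#' composition percentages, CSA log-normal around the type-specific regional
#' means, capillaries Poisson around the regional capillaries-per-fiber mean,
#' and central-nucleus / NADH / SDH flags Bernoulli at the regional
#' percentages. Setting `sd_scale = 0` collapses every draw to its
#' expectation (deterministic tables).
#'
#' The force-frequency curve (5-200 Hz) is a Hill-type sigmoid
#' `f^3 / (f^3 + 45^3)`, normalized to reach the drawn peak torque at 200 Hz,
#' with the 5 Hz entry replaced by the drawn peak twitch.
#'
#' @param n_control,n_vml4,n_vml8 Subjects per group.
#' @param seed Integer seed.
#' @param fibers_per_roi Fibers recorded per 500x500 um region of interest.
#' @param sd_scale Multiplier on all between-subject / between-fiber
#'   variability (0 = deterministic expectations).
#' @return List with tibbles `muscle_function` (one row per subject, wide
#'   `torque_<f>hz` columns) and `fibers` (one row per fiber).
#' @export
#' @examples
#' tt <- generate_terminal_tables(n_control = 2, n_vml4 = 1, n_vml8 = 1,
#'                                seed = 1, fibers_per_roi = 10)
#' names(tt)
generate_terminal_tables <- function(n_control = 16, n_vml4 = 5, n_vml8 = 7,
                                     seed = 1L, fibers_per_roi = 100,
                                     sd_scale = 1) {
  stopifnot(n_control >= 1, n_vml4 >= 1, n_vml8 >= 1, sd_scale >= 0)
  ns <- c(control = n_control, vml_4wk = n_vml4, vml_8wk = n_vml8)
  subjects <- tibble(
    group = rep(names(ns), times = ns),
    subject_id = paste0(rep(names(ns), times = ns), "_",
                        unlist(lapply(ns, seq_len)))
  )
  freqs <- c(5, 10, 20, 40, 60, 80, 100, 150, 200)
  ff_shape <- (freqs^3 / (freqs^3 + 45^3)) / (200^3 / (200^3 + 45^3))
  cal_fn <- muscle_function_calibration()
  cal_hist <- histology_calibration()
  cal_fib <- fiber_calibration()
  sdlog <- 0.35 * sd_scale  # log-normal CSA dispersion between fibers

  withr::with_seed(seed, {
    fun_draws <- subjects |>
      dplyr::left_join(cal_fn, by = "group",
                       relationship = "many-to-many") |>
      dplyr::mutate(value = rnorm(dplyr::n(), .data$mean,
                                  .data$sd * sd_scale)) |>
      dplyr::select("subject_id", "group", "measure", "value") |>
      tidyr::pivot_wider(names_from = "measure", values_from = "value")

    tq <- purrr::map2(fun_draws$peak_torque, fun_draws$peak_twitch,
                      function(pk, tw) {
                        v <- pk * ff_shape
                        v[1] <- tw
                        v
                      })
    tq <- do.call(rbind, tq)
    colnames(tq) <- paste0("torque_", freqs, "hz")
    muscle_function <- dplyr::bind_cols(fun_draws, as_tibble(tq))

    fibers <- tidyr::expand_grid(
      subjects, region = c("lateral", "mid", "medial")
    ) |>
      purrr::pmap(function(group, subject_id, region) {
        fc <- cal_fib[cal_fib$region == region & cal_fib$group == group, ]
        hc <- cal_hist[cal_hist$region == region & cal_hist$group == group, ]
        n <- fibers_per_roi
        if (sd_scale == 0) {
          counts <- allocate_counts(n, fc$pct_type)
          type <- rep(fc$fiber_type, times = counts)
          csa <- rep(fc$mean_csa, times = counts)
          caps <- rep(hc$capillaries_per_fiber, n)
          cn <- seq_len(n) <= round(hc$pct_central_nuclei / 100 * n)
          nadh <- seq_len(n) <= round(hc$pct_nadh_positive / 100 * n)
          sdh <- seq_len(n) <= round(hc$pct_sdh_positive / 100 * n)
        } else {
          type <- sample(fc$fiber_type, n, replace = TRUE,
                         prob = fc$pct_type / sum(fc$pct_type))
          m <- fc$mean_csa[match(type, fc$fiber_type)]
          # meanlog chosen so the log-normal mean equals the published mean
          csa <- rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
          caps <- rpois(n, hc$capillaries_per_fiber)
          cn <- rbinom(n, 1, hc$pct_central_nuclei / 100) == 1
          nadh <- rbinom(n, 1, hc$pct_nadh_positive / 100) == 1
          sdh <- rbinom(n, 1, hc$pct_sdh_positive / 100) == 1
        }
        tibble(subject_id = subject_id, group = group, region = region,
               fiber_type = type, csa = csa, capillaries = caps,
               central_nucleus = cn, nadh_positive = nadh,
               sdh_positive = sdh)
      }) |>
      dplyr::bind_rows()
  })

  list(muscle_function = muscle_function, fibers = fibers)
}
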