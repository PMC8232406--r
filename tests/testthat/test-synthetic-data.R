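# Synthetic generator: preset calibration, determinism, noiseless round
# trips, and parameter recovery of the sampling model.

test_that("built-in presets encode the calibrated study conditions", {
  p <- builtin_presets()
  expect_setequal(names(p), c("baseline", "vml_2wk", "vml_6wk"))

  # baseline phase means solve mean = 19, delta = 4.5
  expect_equal(p$baseline$ee_active_mean, 21.25)
  expect_equal(p$baseline$ee_inactive_mean, 16.75)
  expect_equal(p$baseline$rer_active_mean, 0.93)
  expect_equal(p$baseline$rer_inactive_mean, 0.87)

  # 6-wk: 24-h EE scaled by 0.90, delta preserved; 24-h RER scaled by 0.96
  ee6 <- (p$vml_6wk$ee_active_mean + p$vml_6wk$ee_inactive_mean) / 2
  expect_equal(ee6, 0.90 * 19)
  expect_equal(p$vml_6wk$ee_active_mean - p$vml_6wk$ee_inactive_mean, 4.5)
  rer6 <- (p$vml_6wk$rer_active_mean + p$vml_6wk$rer_inactive_mean) / 2
  expect_equal(rer6, 0.96 * 0.90)

  # 2-wk: EE unchanged, RER mildly reduced
  expect_equal(p$vml_2wk$ee_active_mean, p$baseline$ee_active_mean)
  expect_lt(p$vml_2wk$rer_active_mean, p$baseline$rer_active_mean)
})

test_that("preset invariants are enforced", {
  expect_error(generator_preset("bad", -1, 16, 0.9, 0.9), "EE means")
  expect_error(generator_preset("bad", 21, 16, 1.2, 0.9), "RER means")
  expect_error(generator_preset("bad", 21, 16, 0.9, 0.9, ee_noise_sd = -1),
               "noise sds")
  expect_error(generator_preset("bad", 21, 16, 0.9, 0.9,
                                ar_coefficient = 1), "ar_coefficient")
})

test_that("noiseless calorimetry trace reproduces phase means exactly", {
  s <- noiseless_baseline_series()
  expect_equal(nrow(s), 360)
  b12 <- bin_series(s, 12)
  expect_equal(bin_mean(b12, "ee", "active"), 21.25, tolerance = 1e-12)
  expect_equal(bin_mean(b12, "ee", "inactive"), 16.75, tolerance = 1e-12)
  expect_equal(mean(s$rer), 0.90, tolerance = 1e-12)
  expect_equal(mean(s$ee), 19, tolerance = 1e-12)

  # 6-wk preset: noiseless 24-h EE mean is the scaled target
  s6 <- derive_metabolic_series(generate_calorimetry_trace(
    noiseless(builtin_presets()$vml_6wk), seed = 1))
  expect_equal(mean(s6$ee), 17.1, tolerance = 1e-12)
})

test_that("identical seeds give identical traces, different seeds differ", {
  p <- baseline_preset()
  a <- generate_calorimetry_trace(p, seed = 11)
  b <- generate_calorimetry_trace(p, seed = 11)
  expect_identical(a$vo2, b$vo2)
  expect_identical(a$vco2, b$vco2)
  d <- generate_calorimetry_trace(p, seed = 12)
  expect_false(identical(a$vo2, d$vo2))

  aa <- generate_activity_trace(p, seed = 11)
  bb <- generate_activity_trace(p, seed = 11)
  expect_identical(aa, bb)
})

test_that("activity trace matches its Poisson calibration", {
  p <- baseline_preset()
  at <- generate_activity_trace(p, seed = 3)
  expect_equal(nrow(at), 8640)
  expect_true(all(at$x_amb <= at$x_total & at$y_amb <= at$y_total))

  # zero rates give an all-zero trace
  p0 <- p; p0$amb_rate_active <- 0; p0$amb_rate_inactive <- 0
  at0 <- generate_activity_trace(p0, seed = 3)
  expect_true(all(at0[c("x_total", "x_amb", "y_total", "y_amb",
                        "z_total")] == 0))

  # per-bin counts are Poisson: variance ~ mean in the active phase
  ph <- assign_phase(at$timestamp)
  x <- at$x_amb[ph == "active"]
  expect_equal(var(x) / mean(x), 1, tolerance = 0.08)
})

test_that("cohort generation is deterministic with repeated-measures labels", {
  des <- cohort_design(c(baseline = 3), c("pre", "2wk"),
                       presets = tidyr::expand_grid(
                         group = "baseline", timepoint = c("pre", "2wk")) |>
                         dplyr::mutate(preset = list(baseline_preset())),
                       seed = 5)
  coh1 <- generate_cohort(des)
  coh2 <- generate_cohort(des)
  expect_identical(coh1, coh2)
  expect_equal(nrow(coh1), 6)   # 3 subjects x 2 timepoints
  expect_equal(sort(unique(coh1$subject_id)),
               paste0("baseline_", 1:3))
  # same subject appears at every timepoint
  expect_true(all(table(coh1$subject_id) == 2))
})

test_that("cohort_design rejects inconsistent preset maps", {
  expect_error(cohort_design(c(x = 2), seed = 1), "built-in")
  expect_error(cohort_design(setNames(3, NULL), seed = 1), "named vector")
  bad <- tibble::tibble(group = "g", timepoint = "pre",
                        preset = list(baseline_preset()))
  expect_error(cohort_design(c(g = 2), c("pre", "post"), bad, seed = 1),
               "exactly one preset")
})

test_that("replicate cohorts recover preset targets within 2 SE", {
  # 15 replicate 8-subject cohorts: cheap, unbiased parameter-recovery check
  reps <- purrr::map(1:15, function(r) {
    coh <- generate_cohort(cohort_design(c(baseline = 8), seed = 100 + r))
    m <- cohort_metabolic_metrics(coh)
    a <- cohort_activity_metrics(coh)
    c(ee = mean(m$ee_24h), rer = mean(m$rer_24h), km = mean(a$distance_km))
  })
  reps <- do.call(rbind, reps)
  for (j in seq_len(3)) {
    target <- c(19, 0.90, 1.3)[j]
    se <- sd(reps[, j]) / sqrt(nrow(reps))
    expect_lt(abs(mean(reps[, j]) - target), 2 * se)
  }
})

test_that("terminal tables hit group means when variability is off", {
  tt <- generate_terminal_tables(n_control = 2, n_vml4 = 2, n_vml8 = 2,
                                 seed = 1, fibers_per_roi = 50, sd_scale = 0)
  mf <- tt$muscle_function
  ctl <- mf[mf$group == "control", ]
  expect_true(all(ctl$gastroc_weight_ratio == 1.08))
  expect_true(all(ctl$peak_torque == 19.2))
  expect_true(all(mf$peak_torque[mf$group == "vml_4wk"] == 12.3))
  # torque at 200 Hz is the drawn peak; 5 Hz entry is the twitch
  expect_equal(mf$torque_200hz, mf$peak_torque)
  expect_equal(mf$torque_5hz, mf$peak_twitch)

  # deterministic fiber-type allocation follows the published medial control
  # composition (~59% type IIb)
  fib <- tt$fibers
  med_ctl <- fib[fib$group == "control" & fib$region == "medial", ]
  expect_equal(mean(med_ctl$fiber_type == "IIb"), 0.59, tolerance = 0.02)
})

test_that("stochastic terminal draws are centered on the published means", {
  tt <- generate_terminal_tables(n_control = 60, n_vml4 = 60, n_vml8 = 60,
                                 seed = 2, fibers_per_roi = 40)
  mf <- tt$muscle_function
  expect_equal(mean(mf$gastroc_weight_ratio[mf$group == "control"]), 1.08,
               tolerance = 0.03)
  expect_equal(mean(mf$peak_torque[mf$group == "vml_8wk"]), 9.9,
               tolerance = 0.15)
  # log-normal CSA has the published mean despite skew
  fib <- dplyr::filter(tt$fibers, group == "control", region == "lateral",
                       fiber_type == "IIb")
  expect_equal(mean(fib$csa), 3026.7, tolerance = 0.03 * 3026.7)
})
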