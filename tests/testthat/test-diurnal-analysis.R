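# Phase assignment, binning conservation, moving averages, AUC and the
# flexibility metrics.

test_that("phase assignment follows the half-open light schedule", {
  expect_equal(assign_phase(c("10:00", "20:00", "06:00", "18:00", "05:59")),
               c("inactive", "active", "inactive", "active", "active"))
  ts <- .POSIXct(0, tz = "UTC") + c(0, 12 * 3600)
  expect_equal(assign_phase(ts), c("active", "inactive"))  # 00:00 / 12:00
})

test_that("bin means recombine across widths (conservation)", {
  s <- derive_metabolic_series(
    generate_calorimetry_trace(baseline_preset(), seed = 21))
  for (chan in c("ee", "rer", "carb_ox")) {
    m24 <- bin_mean(bin_series(s, 24), chan)
    m12 <- bin_mean(bin_series(s, 12), chan)
    m6 <- bin_mean(bin_series(s, 6), chan)
    m1 <- bin_mean(bin_series(s, 1), chan)
    expect_equal(mean(m12), m24, tolerance = 1e-12)
    expect_equal(mean(m6), m24, tolerance = 1e-12)
    expect_equal(mean(m1), m24, tolerance = 1e-12)
  }
  # constant channel: every bin mean equals the constant
  s$ee <- 7
  expect_true(all(abs(bin_mean(bin_series(s, 6), "ee") - 7) < 1e-12))
})

test_that("12-h bins carry pure phase labels, 24-h bins are mixed", {
  s <- noiseless_baseline_series()
  b12 <- bin_series(s, 12)
  expect_setequal(unique(b12$phase), c("active", "inactive"))
  expect_equal(unique(bin_series(s, 24)$phase), "mixed")
  b6 <- bin_series(s, 6)
  expect_equal(sort(unique(b6$bin_start)),
               c("00:00", "06:00", "12:00", "18:00"))
  expect_error(bin_series(s[1:100, ], 12), "exactly 24 h")
  expect_error(bin_series(s, 5), "divide 24")
})

test_that("trailing moving average has documented length, lag and linearity", {
  s <- noiseless_baseline_series()
  sm <- moving_average(s, 15)
  expect_equal(nrow(sm), 360 - 15 + 1)           # 346 smoothed points
  expect_identical(sm$timestamp[1], s$timestamp[15])

  # constant in, constant out
  s2 <- s; s2$ee <- 3.5
  expect_true(all(abs(moving_average(s2, 15)$ee - 3.5) < 1e-12))

  # linear ramp with step v: trailing mean lags by 7 steps
  v <- 0.25
  s2$ee <- v * seq_len(360)
  sm2 <- moving_average(s2, 15)
  expect_equal(sm2$ee, v * (15:360) - 7 * v, tolerance = 1e-10)

  # commutes with affine transforms of the channel
  s3 <- s; s3$ee <- 2 * s$ee + 1
  expect_equal(moving_average(s3, 15)$ee, 2 * sm$ee + 1, tolerance = 1e-12)

  expect_error(moving_average(s[1:10, ], 15), "< window")
})

test_that("trapezoidal AUC uses an hour x-axis and is linear", {
  s <- noiseless_baseline_series()
  sm <- moving_average(s, 15)
  # constant 1.0 over the 346 smoothed points spans 345/15 = 23 h
  smc <- sm; smc$ee <- 1
  expect_equal(auc(smc, "ee"), 23.0, tolerance = 1e-12)
  smc$ee <- 0
  expect_equal(auc(smc, "ee"), 0)

  # linearity over random channels
  withr::with_seed(7, {
    f <- rnorm(nrow(sm)); g <- rnorm(nrow(sm))
  })
  sa <- sm; sa$ee <- f
  sb <- sm; sb$ee <- g
  sc <- sm; sc$ee <- 3 * f - 2 * g
  expect_equal(auc(sc, "ee"), 3 * auc(sa, "ee") - 2 * auc(sb, "ee"),
               tolerance = 1e-9)

  expect_error(auc(sm[1, ], "ee"), "at least 2")

  # per-6-h-bin AUCs sum to roughly the 24-h AUC (bin-edge trapezoids only
  # are excluded)
  ab <- auc(sm, "ee", by_bin = TRUE)
  expect_equal(nrow(ab), 5)
  expect_equal(sum(ab$auc[ab$bin_start != "24h"]),
               ab$auc[ab$bin_start == "24h"], tolerance = 0.05)
})

test_that("flexibility metrics reproduce the noiseless preset deltas", {
  s <- noiseless_baseline_series()
  fx <- flexibility_metrics(s)
  expect_equal(fx$delta_ee, 4.5, tolerance = 1e-12)
  expect_equal(fx$delta_rer, 0.06, tolerance = 1e-12)
  expect_gt(fx$auc_ee_24h, 0)
  expect_equal(nrow(fx$auc_6h[[1]]), 4)

  # flat series: all deltas zero
  flat <- s
  flat$ee <- 19; flat$rer <- 0.9
  fx0 <- flexibility_metrics(flat)
  expect_equal(fx0$delta_ee, 0)
  expect_equal(fx0$delta_rer, 0)
})
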