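# Study statistics: ANOVA family, Tukey HSD, chi-squared with pooling.

test_that("one-way ANOVA matches the hand-computable layout", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  # SSB = 6 (df 2), SSW = 6 (df 6): F = MSB/MSW = 3/1
  expect_equal(r$statistic, 3)
  expect_equal(r$df, c(2, 6))
  expect_s3_class(tidy(r), "tbl_df")

  # identical group means with nonzero within-variance: F = 0, p = 1
  r0 <- one_way_anova(list(a = c(1, 3), b = c(2, 2), c = c(0, 4)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
})

test_that("one-way ANOVA with two groups is the pooled t-test (F = t^2)", {
  withr::with_seed(14, {
    x <- rnorm(8); y <- rnorm(10, 0.8)
  })
  r <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("one-way ANOVA p agrees with a permutation oracle on small samples", {
  withr::with_seed(15, {
    g <- list(a = rnorm(5), b = rnorm(5, 1.2), c = rnorm(5))
  })
  r <- one_way_anova(g)
  pooled <- unlist(g)
  labels <- rep(names(g), lengths(g))
  f_of <- function(lab) {
    s <- split(pooled, lab)
    m <- vapply(s, mean, numeric(1)); v <- vapply(s, var, numeric(1))
    n <- lengths(s)
    msb <- sum(n * (m - mean(pooled))^2) / (length(s) - 1)
    msw <- sum((n - 1) * v) / (length(pooled) - length(s))
    msb / msw
  }
  withr::with_seed(16, {
    perm <- replicate(4000, f_of(sample(labels)))
  })
  p_perm <- mean(perm >= r$statistic - 1e-12)
  expect_lt(abs(r$p_value - p_perm),
            2.5 * sqrt(p_perm * (1 - p_perm) / 4000) + 1 / 4000)
})

test_that("repeated-measures ANOVA removes subject effects", {
  withr::with_seed(17, {
    d <- tidyr::expand_grid(subject = paste0("s", 1:6),
                            timepoint = c("pre", "2wk", "6wk"))
    d$y <- rnorm(nrow(d)) + rep(c(0, 0.5, 1.5), times = 6)
  })
  r <- repeated_measures_anova(d, "y", "subject", "timepoint")
  expect_equal(r$df, c(2, 10))   # (t-1), (t-1)(n-1)

  # additive subject shifts leave F unchanged
  d2 <- d
  d2$y <- d$y + rep(rnorm(6, sd = 50), each = 3)
  r2 <- repeated_measures_anova(d2, "y", "subject", "timepoint")
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-8)

  # two timepoints reduce to the paired t-test: F = t^2
  d3 <- dplyr::filter(d, timepoint != "6wk")
  r3 <- repeated_measures_anova(d3, "y", "subject", "timepoint")
  wide <- tidyr::pivot_wider(d3, names_from = timepoint, values_from = y)
  tt <- t.test(wide$pre, wide$`2wk`, paired = TRUE)
  expect_equal(r3$statistic, unname(tt$statistic)^2, tolerance = 1e-10)

  # all-equal-per-subject data: F defined as 0 with p = 1
  d4 <- d; d4$y <- rep(1:6, each = 3)
  r4 <- repeated_measures_anova(d4, "y", "subject", "timepoint")
  expect_equal(r4$statistic, 0)
  expect_equal(r4$p_value, 1)

  expect_error(repeated_measures_anova(d[-1, ], "y", "subject", "timepoint"),
               "incomplete")
})

test_that("two-way ANOVA reports Type-II main effects and interaction", {
  withr::with_seed(18, {
    d <- tidyr::expand_grid(grp = c("ctl", "vml4", "vml8"),
                            ft = c("I", "IIa", "IIb", "IIx"), rep = 1:8)
    d$y <- rnorm(nrow(d)) + ifelse(d$ft == "IIb", 2, 0)  # fiber-type effect only
    d <- d[-(1:5), ]  # unbalance it
  })
  r <- two_way_anova(d, "y", "grp", "ft")
  td <- tidy(r)
  expect_setequal(td$term, c("grp", "ft", "grp:ft"))
  expect_true(td$significant[td$term == "ft"])
  expect_false(td$significant[td$term == "grp:ft"])

  # Type-II SS on the unbalanced layout agrees with the car oracle
  oracle <- car::Anova(lm(y ~ grp * ft, data = d), type = 2)
  expect_equal(td$statistic[td$term == "ft"], oracle["ft", "F value"])

  # single observation per cell: additive model, no interaction row
  d1 <- tidyr::expand_grid(a = c("x", "y", "z"), b = c("u", "v"))
  withr::with_seed(19, d1$y <- rnorm(6) + as.numeric(factor(d1$a)))
  r1 <- two_way_anova(d1, "y", "a", "b")
  expect_setequal(tidy(r1)$term, c("a", "b"))
  a1 <- anova(lm(y ~ a + b, data = d1))
  expect_equal(tidy(r1)$statistic[tidy(r1)$term == "a"], a1["a", "F value"])

  expect_error(two_way_anova(d[d$grp == "ctl", ], "y", "grp", "ft"),
               "2 levels")
  expect_error(two_way_anova(d[!(d$grp == "ctl" & d$ft == "I"), ], "y",
                             "grp", "ft"), "empty")
})

test_that("Tukey HSD flags only pairs involving a shifted group", {
  withr::with_seed(20, {
    g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 10)  # 10 within-SDs
  })
  r <- tukey_hsd(g)
  ph <- r$posthoc
  involving_c <- grepl("c", ph$pair)
  expect_true(all(ph$significant[involving_c]))
  expect_false(any(ph$significant[!involving_c]))

  # two identical groups: adjusted p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(tukey_hsd(same)$posthoc$p_adjusted, 1)

  # Tukey-adjusted p >= unadjusted pairwise t-test p
  p_t <- t.test(g$a, g$b, var.equal = TRUE)$p.value
  expect_gte(ph$p_adjusted[ph$pair == "b-a"], p_t)

  expect_error(tukey_hsd(list(a = c(1, 2))), "2 groups")
})

test_that("chi-squared distribution test matches the hand-worked table", {
  r <- chi_squared_distribution_test(c(10, 20), c(20, 10))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)  # 6.667
  expect_equal(r$df, 1)
  expect_equal(r$alpha, 0.0167)

  # identical histograms: statistic 0, p = 1 (pooling never disturbs a 0)
  r0 <- chi_squared_distribution_test(c(5, 9, 30, 2, 0), c(5, 9, 30, 2, 0))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # sparse tails get pooled until expected counts satisfy Cochran's rule
  a <- c(1, 0, 40, 38, 2, 1)
  b <- c(0, 1, 35, 44, 1, 0)
  r1 <- chi_squared_distribution_test(a, b)
  expect_true(is.finite(r1$statistic))
  expect_lte(r1$df, 3)

  expect_error(chi_squared_distribution_test(c(0, 0), c(1, 2)), "all-zero")
  expect_error(chi_squared_distribution_test(c(1, 2), c(1, 2, 3)),
               "share bin edges")
})

test_that("corrected alpha equals 0.05 over the three group pairs", {
  expect_equal(round(0.05 / 3, 4), 0.0167)
  r <- chi_squared_distribution_test(c(10, 20), c(20, 10))
  expect_true(r$p_value < r$alpha)  # 6.667 on 1 df is significant even corrected
})
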