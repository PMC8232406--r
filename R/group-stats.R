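# The study's statistical plan. Classical machinery (aov/lm, TukeyHSD,
# chisq.test, car's Type-II sums of squares) behind a uniform result object.

new_mf_stat <- function(test, statistic, df, p_value, alpha = 0.05,
                        posthoc = NULL, terms = NULL) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         alpha = alpha, posthoc = posthoc, terms = terms),
    class = "mf_stat"
  )
}

#' @export
print.mf_stat <- function(x, ...) {
  cat("<mf_stat>", x$test, "\n")
  if (!is.null(x$terms)) {
    print(as.data.frame(x$terms), row.names = FALSE)
  } else {
    cat(sprintf("  statistic %.4g, df (%s), p = %.4g (alpha %.4g)\n",
                x$statistic, paste(x$df, collapse = ", "), x$p_value,
                x$alpha))
  }
  if (!is.null(x$posthoc)) {
    cat("  posthoc:\n"); print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mf_stat <- function(x, ...) {
  if (!is.null(x$terms)) {
    dplyr::mutate(x$terms, test = x$test, .before = 1)
  } else {
    tibble(test = x$test, statistic = x$statistic,
           df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
           p_value = x$p_value,
           significant = x$p_value < x$alpha)
  }
}

#' @export
glance.mf_stat <- function(x, ...) {
  tibble(test = x$test, alpha = x$alpha,
         n_posthoc = if (is.null(x$posthoc)) 0L else nrow(x$posthoc))
}

# accept either a data frame + column names or a named list of sample vectors
as_group_df <- function(data, response, group) {
  if (is.data.frame(data)) {
    tibble(value = data[[response]], group = factor(data[[group]]))
  } else {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    tibble(value = unlist(data, use.names = FALSE),
           group = factor(rep(names(data), lengths(data))))
  }
}

#' One-way analysis of variance
#'
#' Classical between/within F test with df (k-1, N-k).
#'
#' @param data Data frame, or a named list of numeric sample vectors.
#' @param response,group Column names (ignored for list input).
#' @param posthoc Run Tukey HSD when the omnibus test is significant.
#' @param alpha Significance level.
#' @return An `mf_stat`; see [tidy()].
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
one_way_anova <- function(data, response = "value", group = "group",
                          posthoc = FALSE, alpha = 0.05) {
  d <- as_group_df(data, response, group)
  if (nlevels(d$group) < 2) abort("need at least 2 groups")
  if (any(table(d$group) < 2)) abort("every group needs n >= 2")
  fit <- aov(value ~ group, data = d)
  a <- summary(fit)[[1]]
  res <- new_mf_stat(
    "one_way_anova",
    statistic = a[["F value"]][1],
    df = c(a[["Df"]][1], a[["Df"]][2]),
    p_value = a[["Pr(>F)"]][1],
    alpha = alpha
  )
  if (posthoc && res$p_value < alpha) {
    res$posthoc <- tukey_hsd(d, "value", "group", alpha = alpha)$posthoc
  }
  res
}

#' One-way repeated-measures analysis of variance
#'
#' Within-subject F test with df (t-1, (t-1)(n-1)); the between-subject
#' effect is removed and sphericity is assumed (no Greenhouse-Geisser
#' correction). Incomplete subject x timepoint matrices are rejected (no
#' imputation).
#'
#' @param data Long data frame.
#' @param response,subject,timepoint Column names.
#' @param alpha Significance level.
#' @return An `mf_stat`.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject = 1:4, timepoint = c("pre", "post"))
#' d$y <- rnorm(nrow(d))
#' repeated_measures_anova(d, "y", "subject", "timepoint")
repeated_measures_anova <- function(data, response = "value",
                                    subject = "subject",
                                    timepoint = "timepoint", alpha = 0.05) {
  d <- tibble(value = data[[response]],
              subject = factor(data[[subject]]),
              timepoint = factor(data[[timepoint]]))
  tab <- table(d$subject, d$timepoint)
  if (any(tab != 1)) {
    abort("incomplete subject x timepoint matrix (each cell needs exactly one value)")
  }
  if (nlevels(d$timepoint) < 2 || nlevels(d$subject) < 2) {
    abort("need >= 2 timepoints and >= 2 subjects")
  }
  # additive two-way layout: residual = subject x time interaction, the
  # standard univariate RM error term
  # perfect-fit warnings arise only in the degenerate all-equal case handled
  # explicitly below
  a <- suppressWarnings(anova(lm(value ~ timepoint + subject, data = d)))
  ms_t <- a["timepoint", "Mean Sq"]; ms_e <- a["Residuals", "Mean Sq"]
  df <- c(a["timepoint", "Df"], a["Residuals", "Df"])
  if (ms_e <= .Machine$double.eps * max(1, abs(ms_t))) {
    f <- if (ms_t <= .Machine$double.eps) 0 else Inf
  } else {
    f <- ms_t / ms_e
  }
  p <- if (f == 0) 1 else stats::pf(f, df[1], df[2], lower.tail = FALSE)
  new_mf_stat("repeated_measures_anova", statistic = f, df = df,
              p_value = p, alpha = alpha)
}

#' Two-way analysis of variance (Type-II sums of squares)
#'
#' Main effects and interaction for two crossed factors; Type-II sums of
#' squares accommodate the unbalanced group sizes. Designs with a single
#' observation per cell are fitted additively (no interaction term is
#' estimable).
#'
#' @param data Data frame.
#' @param response,factor_a,factor_b Column names.
#' @param alpha Significance level.
#' @return An `mf_stat` whose `terms` tibble has one row per model term.
#' @export
#' @examples
#' d <- tidyr::expand_grid(g = c("a", "b"), t = c("I", "IIb"), rep = 1:3)
#' d$y <- rnorm(nrow(d))
#' two_way_anova(d, "y", "g", "t")
two_way_anova <- function(data, response, factor_a, factor_b, alpha = 0.05) {
  d <- tibble(value = data[[response]],
              a = factor(data[[factor_a]]),
              b = factor(data[[factor_b]]))
  if (nlevels(d$a) < 2 || nlevels(d$b) < 2) {
    abort("need >= 2 levels per factor")
  }
  cell <- table(d$a, d$b)
  if (any(cell == 0)) abort("empty factor cell")
  additive <- all(cell == 1)
  fit <- if (additive) lm(value ~ a + b, data = d) else
    lm(value ~ a * b, data = d)
  a2 <- car::Anova(fit, type = 2)
  rows <- setdiff(rownames(a2), "Residuals")
  lab <- c(a = factor_a, b = factor_b,
           `a:b` = paste0(factor_a, ":", factor_b))
  terms <- tibble(
    term = unname(lab[rows]),
    statistic = a2[rows, "F value"],
    df1 = a2[rows, "Df"],
    df2 = a2["Residuals", "Df"],
    p_value = a2[rows, "Pr(>F)"],
    significant = a2[rows, "Pr(>F)"] < alpha
  )
  new_mf_stat("two_way_anova", statistic = NA_real_, df = NA_real_,
              p_value = NA_real_, alpha = alpha, terms = terms)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range adjusted pairwise p-values following a significant
#' omnibus F.
#'
#' @inheritParams one_way_anova
#' @return An `mf_stat` whose `posthoc` tibble has one row per group pair.
#' @export
#' @examples
#' tukey_hsd(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(13, 14, 15)))
tukey_hsd <- function(data, response = "value", group = "group",
                      alpha = 0.05) {
  d <- as_group_df(data, response, group)
  if (nlevels(d$group) < 2) abort("need at least 2 groups")
  fit <- aov(value ~ group, data = d)
  tk <- TukeyHSD(fit)$group
  posthoc <- tibble(
    pair = rownames(tk),
    diff = tk[, "diff"],
    p_adjusted = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha
  )
  a <- summary(fit)[[1]]
  new_mf_stat("tukey_hsd", statistic = a[["F value"]][1],
              df = c(a[["Df"]][1], a[["Df"]][2]),
              p_value = a[["Pr(>F)"]][1], alpha = alpha, posthoc = posthoc)
}

# merge adjacent histogram bins until every expected count is >= 1 and at
# least 80% are >= 5 (Cochran's rule)
pool_bins <- function(mat) {
  repeat {
    if (ncol(mat) <= 1) break
    expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
    if (all(expected >= 1) && mean(expected >= 5) >= 0.8) break
    j <- which.min(colSums(mat))
    nb <- if (j == 1) 2L else j - 1L   # merge into the adjacent bin
    mat[, nb] <- mat[, nb] + mat[, j]
    mat <- mat[, -j, drop = FALSE]
  }
  mat
}

#' Chi-squared comparison of two observed histograms
#'
#' Pearson chi-squared on the 2 x k contingency table of two histograms over
#' identical bin edges (e.g. capillaries-per-fiber or fiber-CSA
#' distributions). Adjacent low-expected-count bins are pooled first (all
#' expected >= 1, >= 80% >= 5). The default alpha 0.0167 is 0.05 corrected
#' for the study's three pairwise group comparisons.
#'
#' @param hist_a,hist_b Non-negative count vectors over the same bins.
#' @param alpha Corrected significance level.
#' @return An `mf_stat`.
#' @export
#' @examples
#' chi_squared_distribution_test(c(10, 20), c(20, 10))
chi_squared_distribution_test <- function(hist_a, hist_b, alpha = 0.0167) {
  if (length(hist_a) != length(hist_b)) {
    abort("histograms must share bin edges")
  }
  if (sum(hist_a) == 0 || sum(hist_b) == 0) abort("all-zero histogram")
  mat <- pool_bins(rbind(hist_a, hist_b))
  if (ncol(mat) < 2) {
    abort("histograms collapse to a single bin after pooling")
  }
  ct <- suppressWarnings(chisq.test(mat, correct = FALSE))
  new_mf_stat("chi_squared_distribution", statistic = unname(ct$statistic),
              df = unname(ct$parameter), p_value = unname(ct$p.value),
              alpha = alpha)
}
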