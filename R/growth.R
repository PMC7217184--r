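## Growth statistics: per-group linear regression of DSM markers (PC1,
## signature weight) against age, and sequential F-tests comparing slopes
## and, when slopes agree, intercepts between two groups.

#' Ordinary least-squares line fit
#'
#' @param x Ages (n >= 3, not all equal).
#' @param y Response (e.g. PC1 score or signature weight).
#' @return List: `slope`, `intercept`, `rss`, `n`, `fit` (the `lm`).
#' @export
fit_line <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need n >= 3 paired observations")
  if (stats::sd(x) == 0) stop("degenerate x: all ages equal")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       rss = sum(stats::residuals(fit)^2), n = length(x), fit = fit)
}

f_test_nested <- function(rss_red, rss_full, df_red, df_full) {
  # F-test of a reduced against a full nested linear model, with explicit
  # handling of the zero-residual degeneracies (exact fits)
  d_rss <- max(rss_red - rss_full, 0)
  d_df <- df_red - df_full
  eps <- 1e-12 * max(rss_red, 1)
  if (d_rss <= eps) return(list(F = 0, p = 1))
  if (rss_full <= eps) return(list(F = Inf, p = 0))
  F_ <- (d_rss / d_df) / (rss_full / df_full)
  list(F = F_, p = stats::pf(F_, d_df, df_full, lower.tail = FALSE))
}

#' Compare regression lines between two groups
#'
#' Fits separate regressions of `y` on `x` per group and applies the
#' sequential slope-then-intercept procedure: an F-test of equal slopes
#' (common-slope model vs. full interaction model); only when the slopes do
#' not differ at `alpha` is the intercept difference tested (common-slope
#' model vs. single common line). The decision trace records which test was
#' applicable.
#'
#' @param x_a,y_a,x_b,y_b Per-group ages and responses (each n >= 3).
#' @param alpha Significance level gating the intercept test (default 0.05).
#' @param labels Length-2 group labels.
#' @return A `regression_comparison`: per-group fits, `slope_test`
#'   (`F`, `p`), `intercept_test` (`F`, `p`, or `NA` when not applicable),
#'   `decision`.
#' @export
compare_regressions <- function(x_a, y_a, x_b, y_b, alpha = 0.05,
                                labels = c("A", "B")) {
  fa <- fit_line(x_a, y_a)
  fb <- fit_line(x_b, y_b)
  x <- c(x_a, x_b); y <- c(y_a, y_b)
  g <- factor(rep(labels, c(length(x_a), length(x_b))))
  n <- length(x)
  rss_full <- fa$rss + fb$rss                       # separate lines
  rss_slope <- sum(stats::residuals(stats::lm(y ~ x + g))^2)  # common slope
  rss_common <- sum(stats::residuals(stats::lm(y ~ x))^2)     # single line
  slope_test <- f_test_nested(rss_slope, rss_full, n - 3L, n - 4L)
  if (slope_test$p >= alpha) {
    intercept_test <- f_test_nested(rss_common, rss_slope, n - 2L, n - 3L)
    decision <- sprintf(
      "slopes not significantly different (p = %.4g); intercepts tested under common slope (p = %.4g)",
      slope_test$p, intercept_test$p)
  } else {
    intercept_test <- list(F = NA_real_, p = NA_real_)
    decision <- sprintf(
      "slopes differ significantly (p = %.4g); intercept test not applicable",
      slope_test$p)
  }
  structure(list(groups = stats::setNames(list(
    list(slope = fa$slope, intercept = fa$intercept, n = fa$n, rss = fa$rss),
    list(slope = fb$slope, intercept = fb$intercept, n = fb$n, rss = fb$rss)),
    labels),
    slope_test = slope_test, intercept_test = intercept_test,
    alpha = alpha, decision = decision),
    class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("Regression comparison:\n")
  for (g in names(x$groups)) {
    f <- x$groups[[g]]
    cat(sprintf("  %-10s slope %.4g, intercept %.4g (n = %d)\n",
                g, f$slope, f$intercept, f$n))
  }
  cat(sprintf("  slope test:     F = %.4g, p = %.4g\n",
              x$slope_test$F, x$slope_test$p))
  if (!is.na(x$intercept_test$p))
    cat(sprintf("  intercept test: F = %.4g, p = %.4g\n",
                x$intercept_test$F, x$intercept_test$p))
  cat(" ", x$decision, "\n")
  invisible(x)
}

#' Align PC1 with age
#'
#' PCA mode signs are arbitrary; flips the sign of a PC1 score vector so it
#' correlates positively with age, making regression slopes comparable
#' across runs.
#'
#' @param pc1 PC1 scores.
#' @param age Ages.
#' @return Possibly sign-flipped `pc1`.
#' @export
align_pc1_with_age <- function(pc1, age) {
  r <- suppressWarnings(stats::cor(pc1, age))
  if (!is.na(r) && r < 0) -pc1 else pc1
}

#' Growth comparison of PC1 against age between two groups
#'
#' Projects all faces of both groups into one DSM, aligns PC1 positively
#' with age, and runs [compare_regressions()] on PC1 vs. age.
#'
#' @param cc A `corresponded_cohort` containing both groups.
#' @param group_a,group_b Group labels.
#' @param model Optional pre-fit [dsm()] (default: fit on the two groups).
#' @param alpha Passed to [compare_regressions()].
#' @return A `regression_comparison` plus a `data` attribute with the
#'   per-subject (age, PC1, group) table.
#' @export
pc1_growth_comparison <- function(cc, group_a, group_b, model = NULL,
                                  alpha = 0.05) {
  sel <- cc$meta$group %in% c(group_a, group_b)
  if (is.null(model)) model <- dsm(cc$points[sel])
  scores <- predict(model, cc$points[sel])
  pc1 <- align_pc1_with_age(scores[, 1], cc$meta$age[sel])
  grp <- cc$meta$group[sel]
  res <- compare_regressions(cc$meta$age[sel][grp == group_a],
                             pc1[grp == group_a],
                             cc$meta$age[sel][grp == group_b],
                             pc1[grp == group_b],
                             alpha = alpha, labels = c(group_a, group_b))
  attr(res, "data") <- data.frame(subject_id = cc$meta$subject_id[sel],
                                  age = cc$meta$age[sel], pc1 = pc1,
                                  group = grp, stringsAsFactors = FALSE)
  res
}

#' Dysmorphism trend: signature weight against age
#'
#' Applies the slope/intercept comparison machinery to signature weight vs.
#' age for two groups, and additionally reports the between-group
#' mean-weight Student's t-test (used e.g. for male-vs-female dysmorphism
#' comparisons).
#'
#' @param weights Per-subject signature weights.
#' @param ages Per-subject ages.
#' @param groups Per-subject group labels (exactly 2 distinct).
#' @param alpha Passed to [compare_regressions()].
#' @return A `regression_comparison` with an extra `weight_test`
#'   (`group_comparison`) element.
#' @export
dysmorphism_trend <- function(weights, ages, groups, alpha = 0.05) {
  labs <- sort(unique(as.character(groups)))
  if (length(labs) != 2L) stop("need exactly 2 groups, got ",
                               length(labs))
  a <- groups == labs[1]; b <- groups == labs[2]
  res <- compare_regressions(ages[a], weights[a], ages[b], weights[b],
                             alpha = alpha, labels = labs)
  res$weight_test <- compare_groups(weights[a], weights[b], threshold = alpha,
                                    measurement = "signature_weight")
  res
}
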