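test_that("line fitting is exact ordinary least squares", {
  x <- c(1, 2, 4, 7, 9)
  f <- fit_line(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-12)
  f0 <- fit_line(x, rep(3, 5))
  expect_equal(f0$slope, 0)
  # normal-equations oracle on random data
  set.seed(14)
  for (rep in 1:20) {
    xs <- rnorm(sample(5:30, 1)); ys <- rnorm(length(xs))
    f <- fit_line(xs, ys)
    Sxx <- sum((xs - mean(xs))^2)
    b <- sum((xs - mean(xs)) * (ys - mean(ys))) / Sxx
    a <- mean(ys) - b * mean(xs)
    expect_equal(f$slope, b, tolerance = 1e-10)
    expect_equal(f$intercept, a, tolerance = 1e-10)
  }
  expect_error(fit_line(rep(2, 5), 1:5), "degenerate")
  expect_error(fit_line(1:2, 1:2), "n >= 3")
})

test_that("slope/intercept comparison follows the sequential procedure", {
  # identical data in both groups: both tests null
  x <- c(1, 3, 5, 7); y <- c(2, 5, 9, 13)
  r <- compare_regressions(x, y, x, y)
  expect_equal(r$slope_test$F, 0)
  expect_equal(r$slope_test$p, 1)
  expect_equal(r$intercept_test$p, 1)

  # exactly parallel noiseless lines: slope F = 0, intercept p -> 0
  r2 <- compare_regressions(x, 2 * x + 1, x, 2 * x + 6)
  expect_equal(r2$slope_test$F, 0)
  expect_lt(r2$intercept_test$p, 1e-12)
  expect_match(r2$decision, "intercepts tested")

  # clearly different slopes: intercept test is withheld
  set.seed(15)
  xa <- runif(30, 0, 10); xb <- runif(30, 0, 10)
  r3 <- compare_regressions(xa, 1 + 0.2 * xa + rnorm(30, 0, 0.1),
                            xb, 1 + 2.0 * xb + rnorm(30, 0, 0.1))
  expect_lt(r3$slope_test$p, 1e-6)
  expect_true(is.na(r3$intercept_test$p))
  expect_match(r3$decision, "not applicable")
})

test_that("comparison F statistics match an explicit design-matrix oracle", {
  rss_of <- function(X, y) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  set.seed(16)
  for (rep in 1:15) {
    na <- sample(6:15, 1); nb <- sample(6:15, 1)
    xa <- rnorm(na); ya <- 1 + 0.5 * xa + rnorm(na, 0, 0.8)
    xb <- rnorm(nb); yb <- 0.5 + 0.9 * xb + rnorm(nb, 0, 0.8)
    r <- compare_regressions(xa, ya, xb, yb)
    x <- c(xa, xb); y <- c(ya, yb); g <- rep(0:1, c(na, nb))
    n <- na + nb
    rss_full <- rss_of(cbind(1, x, g, x * g), y)
    rss_slope <- rss_of(cbind(1, x, g), y)
    rss_common <- rss_of(cbind(1, x), y)
    F_slope <- (rss_slope - rss_full) / (rss_full / (n - 4))
    expect_equal(r$slope_test$F, F_slope, tolerance = 1e-8)
    expect_equal(r$slope_test$p, pf(F_slope, 1, n - 4, lower.tail = FALSE),
                 tolerance = 1e-8)
    if (!is.na(r$intercept_test$F)) {
      F_int <- (rss_common - rss_slope) / (rss_slope / (n - 3))
      expect_equal(r$intercept_test$F, F_int, tolerance = 1e-8)
    }
  }
})

test_that("an intercept offset between groups is detected with high power", {
  # markers simulated at the regression level: common slope, +3 offset,
  # noise SD 0.2, n = 40 per group
  set.seed(17)
  hits <- 0L
  for (r in 1:200) {
    xa <- runif(40, 2, 22); xb <- runif(40, 2, 22)
    ya <- 1 + 0.5 * xa + rnorm(40, 0, 0.2)
    yb <- 4 + 0.5 * xb + rnorm(40, 0, 0.2)
    cmp <- compare_regressions(xa, ya, xb, yb)
    # the sequential procedure reports a difference in slope and/or
    # intercept; either branch counts as detecting the offset
    hits <- hits + ((!is.na(cmp$intercept_test$p) &&
                       cmp$intercept_test$p < 0.05) ||
                      cmp$slope_test$p < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("dysmorphism trends: degenerate and constructed cases", {
  ages <- c(2, 6, 10, 14, 18, 22)
  # all weights equal: zero slopes, no differences
  r0 <- dysmorphism_trend(rep(5, 12), c(ages, ages),
                          rep(c("a", "b"), each = 6))
  expect_equal(r0$groups$a$slope, 0)
  expect_equal(r0$groups$b$slope, 0)
  expect_equal(r0$slope_test$F, 0)
  # weight rises with age in group b only (noiseless): slope difference
  r1 <- dysmorphism_trend(c(rep(3, 6), 3 + 0.5 * ages), c(ages, ages),
                          rep(c("a", "b"), each = 6))
  expect_lt(r1$slope_test$p, 1e-10)
  expect_equal(r1$groups$b$slope, 0.5, tolerance = 1e-9)
  expect_s3_class(r1$weight_test, "group_comparison")
  expect_error(dysmorphism_trend(1:6, 1:6, rep("a", 6)), "2 groups")
})

test_that("an age-ramped effect produces a rising patient dysmorphism slope", {
  ramp_fields <- lapply(syndrome_effect_fields(3), function(f) {
    f$age_ramp_a0 <- 22  # amplitude grows linearly over the age range
    f
  })
  cfg <- cohort_config(groups = list(
    control = list(n = 20, age_range = c(2, 22), growth = c(1, 0)),
    CS = list(n = 16, age_range = c(2, 22), growth = c(1, 0),
              effects = ramp_fields)),
    resolution = 700, seed = 19)
  cc <- correspond_cohort(generate_cohort(cfg, template = fix_template(700)))
  w <- cohort_signature_weights(cc, k = 12)
  r <- dysmorphism_trend(w$weight, w$age, w$group)
  expect_gt(r$groups$CS$slope, 0)
  expect_gt(r$groups$CS$slope, r$groups$control$slope)
})

test_that("PC1 growth comparison recovers the faster patient growth model", {
  cc <- fix_study_cc()  # CS grows faster by construction
  r <- pc1_growth_comparison(cc, "control", "CS")
  d <- attr(r, "data")
  expect_gt(cor(d$pc1, d$age), 0.8)   # PC1 tracks age after sign alignment
  expect_gt(r$groups$CS$slope, r$groups$control$slope)
})
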