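# Independent oracles used here: the closed-form t statistic with the
# regularized-incomplete-beta tail (pbeta identity) for p-values, and
# stats::t.test as a second route.

t_p_via_beta <- function(stat, df) {
  # two-sided p from the regularized incomplete beta: P(|T| > t)
  stats::pbeta(df / (df + stat^2), df / 2, 1 / 2)
}

test_that("t-intervals match the closed form and degenerate correctly", {
  # symmetry about the mean
  ci0 <- ci_mean_t(0, 1, 4, 0.90)
  expect_equal(ci0$ci_low, -ci0$ci_high)
  # zero SD gives a zero-width interval
  ciz <- group_summary(rep(5, 10), 0.90)
  expect_equal(ciz$ci_low, 5)
  expect_equal(ciz$ci_high, 5)
  expect_equal(ciz$sd, 0)
  # group_summary and ci_mean_t agree on raw data
  set.seed(5)
  x <- rnorm(17, 100, 25)
  gs <- group_summary(x, 0.90)
  ci <- ci_mean_t(mean(x), sd(x), length(x), 0.90)
  expect_equal(gs$ci_low, ci$ci_low)
  expect_equal(gs$ci_high, ci$ci_high)
  expect_error(group_summary(3), "n < 2")
  expect_error(ci_mean_t(0, 1, 5, 1.2), "conf_level")
})

test_that("paired t equals the direct formula and incomplete-beta p", {
  set.seed(23)
  for (rep in 1:5) {
    pre <- rnorm(10, 1000, 300)
    post <- pre + rnorm(10, 200, 150)
    res <- paired_t(pre, post)
    d <- post - pre
    stat <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(res$statistic, stat, tolerance = 1e-12)
    expect_equal(res$p_value, t_p_via_beta(stat, 9), tolerance = 1e-10)
    # one-sample special case: same p as stats::t.test on differences
    expect_equal(res$p_value, t.test(d)$p.value, tolerance = 1e-10)
  }
  # null case and degenerate variance
  expect_equal(paired_t(1:5, 1:5)$p_value, 1)
  expect_equal(paired_t(1:5, 1:5)$statistic, 0)
  degen <- paired_t(c(100, 200, 300), c(110, 210, 310))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("unpaired t matches the hand-computed pooled form and t.test", {
  a <- c(0, 0, 1, 1); b <- c(10, 10, 11, 11)
  res <- independent_t(a, b)
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$statistic, stat, tolerance = 1e-12)
  expect_equal(res$df, 6)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  # translation invariance
  shifted <- independent_t(a + 500, b + 500)
  expect_equal(shifted$statistic, res$statistic)
  # identical samples
  expect_equal(independent_t(a, a)$statistic, 0)
  expect_equal(independent_t(a, a)$p_value, 1)
  # Welch variant agrees with t.test default
  set.seed(9)
  x <- rnorm(8, 0, 1); y <- rnorm(12, 1, 3)
  w <- independent_t(x, y, var_equal = FALSE)
  tw <- t.test(x, y)
  expect_equal(w$statistic, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(tw$parameter), tolerance = 1e-10)
  expect_equal(w$p_value, tw$p.value, tolerance = 1e-10)
  expect_error(independent_t(1, 1:4), "n >= 2")
})

test_that("Bonferroni threshold is alpha over k", {
  expect_equal(bonferroni_alpha(0.05, 6), 0.05 / 6)
  expect_equal(round(bonferroni_alpha(0.05, 6), 3), 0.008)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "k")
})

test_that("effect-size bands partition the d axis without gaps", {
  expect_equal(classify_effect(c(0, 0.19, 0.2, 0.49, 0.5, 0.79, 0.8,
                                 1.19, 1.2, 2.0, 2.01, 2.59)),
               c("trivial", "trivial", "small", "small", "moderate",
                 "moderate", "large", "large", "very large", "very large",
                 "huge", "huge"))
  # sign is ignored; every finite d gets exactly one band
  set.seed(31)
  d <- c(rnorm(200, 0, 2), -0.2, 0.2)
  expect_identical(classify_effect(d), classify_effect(-d))
  expect_false(anyNA(classify_effect(d)))
})

test_that("pre/post Cohen's d uses the RMS-of-SDs denominator", {
  # equal SDs collapse to (delta mean)/s exactly
  es <- cohen_d_prepost(100, 50, 130, 50)
  expect_equal(es$d, 30 / 50)
  expect_equal(es$band, "moderate")
  # equal means are trivial
  expect_equal(cohen_d_prepost(100, 30, 100, 60)$d, 0)
  expect_equal(cohen_d_prepost(100, 30, 100, 60)$band, "trivial")
  expect_error(cohen_d_prepost(1, 0, 2, 0), "both SDs")
})

test_that("independent Cohen's d is symmetric and translation invariant", {
  base <- cohen_d_independent(67, 33, 6, 364, 248, 23)
  flipped <- cohen_d_independent(364, 248, 23, 67, 33, 6)
  expect_equal(base$d, flipped$d)
  shifted <- cohen_d_independent(67 + 300, 33, 6, 364 + 300, 248, 23)
  expect_equal(base$d, shifted$d)
  expect_equal(cohen_d_independent(5, 2, 4, 5, 3, 9)$d, 0)
  expect_error(cohen_d_independent(1, 0, 3, 2, 0, 3), "pooled variance")
})

test_that("both percent-improvement conventions behave as defined", {
  expect_equal(percent_improvement_of_means(560, 969), 100 * 560 / 969)
  expect_equal(percent_improvement_of_means(0, 1000), 0)
  expect_error(percent_improvement_of_means(100, 0), "mean_pre")

  two <- tibble::tibble(pre_yoyo_m = c(100, 200), post_yoyo_m = c(150, 200))
  expect_equal(mean_individual_percent_improvement(two), 25)
  same <- tibble::tibble(pre_yoyo_m = c(480, 720), post_yoyo_m = c(480, 720))
  expect_equal(mean_individual_percent_improvement(same), 0)
  # oracle: direct average of per-subject ratios on a random cohort
  set.seed(77)
  coh <- tibble::tibble(pre_yoyo_m = runif(30, 400, 2000))
  coh$post_yoyo_m <- coh$pre_yoyo_m + rnorm(30, 300, 200)
  expect_equal(mean_individual_percent_improvement(coh),
               mean(100 * (coh$post_yoyo_m - coh$pre_yoyo_m) / coh$pre_yoyo_m))
  zero <- tibble::tibble(pre_yoyo_m = c(0, 100), post_yoyo_m = c(10, 150))
  expect_error(mean_individual_percent_improvement(zero), "pre_yoyo_m")
})

test_that("responder counts use strict thresholds", {
  rc <- responder_counts(c(100, 130, 600), thresholds = c(120, 500))
  expect_equal(rc$count, c(2L, 1L))
  expect_equal(rc$proportion, c(2 / 3, 1 / 3))
  # boundary value is not a responder (strictly greater)
  expect_equal(responder_counts(c(120, 121), 120)$count, 1L)
  empty <- responder_counts(numeric(0), c(120, 500))
  expect_equal(empty$count, c(0L, 0L))
  expect_true(all(is.na(empty$proportion)))
  expect_error(responder_counts(1:3, numeric(0)), "non-empty")
})
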