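# Independent oracle for the split-plot decomposition: stats::aov with an
# Error(subject) stratum on long-format data. Our implementation works from
# per-subject difference scores and subject means; aov fits the full
# mixed-model design matrix, so agreement is a genuine cross-check.

aov_oracle <- function(df) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(df, subject = factor(dplyr::row_number())),
    c("pre_yoyo_m", "post_yoyo_m"), names_to = "time", values_to = "y"
  )
  long$time <- factor(long$time, levels = c("pre_yoyo_m", "post_yoyo_m"))
  long$stratum <- factor(long$stratum)
  fit <- stats::aov(y ~ stratum * time + Error(subject), data = long)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  list(
    f_group = between["stratum", "F value"],
    f_time = within["time", "F value"],
    f_int = within["stratum:time", "F value"],
    ss_berr = between["Residuals", "Sum Sq"],
    ss_werr = within["Residuals", "Sum Sq"]
  )
}

balanced_cohort <- function(n_per = 8, seed = 13) {
  set.seed(seed)
  purrr::map_dfr(c("low", "medium", "high"), function(g) {
    shift <- switch(g, low = 50, medium = 300, high = 550)
    pre <- rnorm(n_per, 1000, 300)
    tibble::tibble(stratum = g, pre_yoyo_m = pre,
                   post_yoyo_m = pre + shift + rnorm(n_per, 0, 150))
  })
}

test_that("balanced split-plot decomposition matches the aov oracle", {
  df <- balanced_cohort()
  res <- tidy(split_plot_anova(df))
  orc <- aov_oracle(df)
  grab <- function(eff, col) res[[col]][res$effect == eff]
  expect_equal(grab("group", "statistic"), orc$f_group, tolerance = 1e-8)
  expect_equal(grab("time", "statistic"), orc$f_time, tolerance = 1e-8)
  expect_equal(grab("group:time", "statistic"), orc$f_int, tolerance = 1e-8)
  expect_equal(grab("subjects within groups", "ss"), orc$ss_berr,
               tolerance = 1e-8)
  expect_equal(grab("time x subjects within groups", "ss"), orc$ss_werr,
               tolerance = 1e-8)
  # df decomposition sums to 2N - 1
  expect_equal(sum(res$df) + 1, 2 * nrow(df))  # +1 for the time row's pair
})

test_that("balanced designs make Type III and weighted variants coincide", {
  df <- balanced_cohort(n_per = 6, seed = 29)
  t3 <- tidy(split_plot_anova(df, type = "III"))
  tw <- tidy(split_plot_anova(df, type = "weighted"))
  expect_equal(t3$ss, tw$ss, tolerance = 1e-8)
  expect_equal(t3$statistic, tw$statistic, tolerance = 1e-8)
})

test_that("no-variation data yields zero test sums of squares", {
  df <- tibble::tibble(
    stratum = rep(c("low", "high"), each = 3),
    pre_yoyo_m = 1000, post_yoyo_m = 1000
  )
  res <- tidy(split_plot_anova(df))
  expect_equal(res$ss[res$effect %in% c("group", "time", "group:time")],
               c(0, 0, 0))
})

test_that("constant shifts move only the effects they should", {
  df <- balanced_cohort(n_per = 5, seed = 3)
  base <- tidy(split_plot_anova(df))
  grab <- function(res, eff) res$statistic[res$effect == eff]

  # adding a constant to every observation changes no F
  all_shift <- df
  all_shift$pre_yoyo_m <- all_shift$pre_yoyo_m + 250
  all_shift$post_yoyo_m <- all_shift$post_yoyo_m + 250
  shifted <- tidy(split_plot_anova(all_shift))
  for (eff in c("group", "time", "group:time")) {
    expect_equal(grab(shifted, eff), grab(base, eff), tolerance = 1e-10)
  }

  # adding a constant to both time points of one group changes group F only
  one_grp <- df
  sel <- one_grp$stratum == "medium"
  one_grp$pre_yoyo_m[sel] <- one_grp$pre_yoyo_m[sel] + 400
  one_grp$post_yoyo_m[sel] <- one_grp$post_yoyo_m[sel] + 400
  moved <- tidy(split_plot_anova(one_grp))
  expect_equal(grab(moved, "time"), grab(base, "time"), tolerance = 1e-10)
  expect_equal(grab(moved, "group:time"), grab(base, "group:time"),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(grab(moved, "group"), grab(base, "group"))))
})

test_that("two-group interaction F is the squared pooled t on differences", {
  set.seed(17)
  df <- tibble::tibble(
    stratum = rep(c("low", "high"), times = c(7, 11)),
    pre_yoyo_m = rnorm(18, 1000, 250)
  )
  df$post_yoyo_m <- df$pre_yoyo_m +
    ifelse(df$stratum == "low", 80, 450) + rnorm(18, 0, 180)
  res <- tidy(split_plot_anova(df, type = "weighted"))
  d <- df$post_yoyo_m - df$pre_yoyo_m
  tt <- independent_t(d[df$stratum == "low"], d[df$stratum == "high"])
  expect_equal(res$statistic[res$effect == "group:time"], tt$statistic^2,
               tolerance = 1e-8)
})

test_that("summary-based ANOVA agrees with raw data built to match exactly", {
  means <- c(67, 364, 560); sds <- c(33, 248, 225); ns <- c(6, 23, 13)
  df <- cohort_from_diff_summaries(means, sds, ns)
  for (type in c("III", "weighted")) {
    from_sum <- tidy(anova_from_summaries(means, sds, ns, type = type))
    from_raw <- tidy(split_plot_anova(df, type = type))
    for (eff in c("time", "group:time")) {
      expect_equal(from_sum$statistic[from_sum$effect == eff],
                   from_raw$statistic[from_raw$effect == eff],
                   tolerance = 1e-8)
    }
  }
  # the study's group sizes give the printed df pattern: time (1, 39),
  # interaction (2, 39)
  res <- anova_from_summaries(means, sds, ns)
  tab <- tidy(res)
  expect_equal(tab$df[tab$effect == "time"], 1)
  expect_equal(tab$df[tab$effect == "group:time"], 2)
  expect_equal(tab$df[tab$effect == "time x subjects within groups"], 39)
  expect_true(res$partial)

  # degenerate inputs
  zero <- tidy(anova_from_summaries(c(0, 0), c(10, 12), c(5, 7)))
  expect_equal(zero$statistic[zero$effect == "time"], 0)
  expect_equal(zero$statistic[zero$effect == "group:time"], 0)
  one <- tidy(anova_from_summaries(100, 50, 8))
  d_t <- paired_t(rep(0, 8), exact_sample(8, 100, 50, seed = 1))
  expect_equal(one$statistic[one$effect == "time"], d_t$statistic^2,
               tolerance = 1e-8)
  expect_error(anova_from_summaries(c(1, 2), c(1, 2, 3), c(4, 4)),
               "equal length")
})

test_that("Tukey-Kramer q and p behave correctly at the extremes", {
  set.seed(41)
  same <- rnorm(10, 100, 20)
  res <- tukey_hsd(list(a = same, b = same))
  expect_equal(res$q, 0)
  expect_equal(res$adj_p_value, 1)

  groups <- list(a = rnorm(8, 0, 1), b = rnorm(8, 0, 1),
                 c = rnorm(8, 50, 1))
  res3 <- tukey_hsd(groups)
  expect_equal(nrow(res3), 3)  # all unordered pairs
  expect_lt(res3$adj_p_value[res3$group1 == "a" & res3$group2 == "c"], 0.001)
  expect_gt(res3$adj_p_value[res3$group1 == "a" & res3$group2 == "b"], 0.2)
  expect_error(tukey_hsd(list(a = 1:3)), "2 groups")
  expect_error(tukey_hsd(list(a = 1:3, b = 4:6), mse = 0, df_error = 4),
               "MSE")
})

test_that("Tukey adjusted p matches a Monte-Carlo studentized-range oracle", {
  set.seed(57)
  n_per <- 9
  groups <- list(a = rnorm(n_per, 0, 30), b = rnorm(n_per, 25, 30),
                 c = rnorm(n_per, 55, 30))
  res <- tukey_hsd(groups)
  k <- 3; df_err <- 3 * (n_per - 1)
  mse <- sum(vapply(groups, function(g) (n_per - 1) * var(g), numeric(1))) /
    df_err
  # MC draw of the studentized range of k iid normal means
  B <- 1e6
  z1 <- rnorm(B); z2 <- rnorm(B); z3 <- rnorm(B)
  rng <- pmax(z1, z2, z3) - pmin(z1, z2, z3)
  s <- sqrt(rchisq(B, df_err) / df_err)
  qstar <- rng / s
  for (i in seq_len(nrow(res))) {
    p_mc <- mean(qstar >= res$q[i])
    se_mc <- sqrt(max(p_mc * (1 - p_mc), 1e-9) / B)
    expect_lt(abs(res$adj_p_value[i] - p_mc), max(4 * se_mc, 5e-4))
  }
})
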