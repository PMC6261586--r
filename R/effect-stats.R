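# Group summaries, t-tests, Cohen's d, Bonferroni threshold, percent
# improvements and responder counts. Statistical code never rounds; report-time
# formatting lives in render_report().

#' Mean, SD and central-t confidence interval for a sample
#'
#' @param values Numeric vector (metres in the Yo-Yo context, but unit-free).
#' @param conf_level Two-sided confidence level, default 0.90.
#' @param label Optional group label carried into the output.
#' @return One-row tibble: `label`, `n`, `mean`, `sd` (sample SD, n-1
#'   denominator), `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' group_summary(c(40, 60, 80, 100, 60, 62), conf_level = 0.90)
#' @export
group_summary <- function(values, conf_level = 0.90, label = "all") {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("confidence interval undefined for n < 2", call. = FALSE)
  ci <- ci_mean_t(mean(values), stats::sd(values), n, conf_level)
  tibble::tibble(
    label = label, n = n, mean = ci$mean, sd = stats::sd(values),
    ci_low = ci$ci_low, ci_high = ci$ci_high, conf_level = conf_level
  )
}

#' t-interval for a mean from printed summary statistics
#'
#' Computes `mean +/- t_{(1+conf)/2, n-1} * sd / sqrt(n)`, the same interval
#' [group_summary()] derives from raw values. Taking mean/SD/n directly lets
#' published tables be reproduced without subject-level data.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (n-1 denominator).
#' @param n Sample size (>= 2).
#' @param conf_level Two-sided confidence level, default 0.90.
#' @return One-row tibble: `mean`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' ci_mean_t(67, 33, 6)    # the low-stratum improvement interval, ~ (40, 94)
#' ci_mean_t(560, 225, 13) # the high stratum, ~ (449, 671)
#' @export
ci_mean_t <- function(mean, sd, n, conf_level = 0.90) {
  if (n < 2L) stop("confidence interval undefined for n < 2", call. = FALSE)
  if (conf_level <= 0 || conf_level >= 1) {
    stop("conf_level must lie in (0, 1)", call. = FALSE)
  }
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  half <- stats::qt((1 + conf_level) / 2, df = n - 1) * sd / sqrt(n)
  tibble::tibble(mean = mean, ci_low = mean - half, ci_high = mean + half,
                 conf_level = conf_level)
}

t_result <- function(statistic, df, p, alpha_adjusted, degenerate = FALSE) {
  tibble::tibble(statistic = statistic, df = df, p_value = p,
                 alpha_adjusted = alpha_adjusted, degenerate = degenerate)
}

#' Paired t-test on pre/post measurements
#'
#' One-sample t on the differences `post - pre`, two-sided. Zero-variance
#' non-zero differences (every subject changed by exactly the same amount)
#' yield an unbounded statistic; the result is returned with `p_value = 0` and
#' `degenerate = TRUE` rather than an error.
#'
#' @param pre,post Equal-length numeric vectors, aligned by subject.
#' @param alpha_adjusted Significance threshold recorded in the result
#'   (e.g. a Bonferroni-corrected alpha); informational only.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `alpha_adjusted`,
#'   `degenerate`.
#' @export
paired_t <- function(pre, post, alpha_adjusted = 0.05) {
  if (length(pre) != length(post)) {
    stop("pre and post must have equal length", call. = FALSE)
  }
  n <- length(pre)
  if (n < 2L) stop("paired t-test requires n >= 2", call. = FALSE)
  d <- post - pre
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    if (mean(d) == 0) return(t_result(0, df, 1, alpha_adjusted))
    return(t_result(sign(mean(d)) * Inf, df, 0, alpha_adjusted,
                    degenerate = TRUE))
  }
  stat <- mean(d) / (s / sqrt(n))
  t_result(stat, df, 2 * stats::pt(-abs(stat), df), alpha_adjusted)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance test by default (`df = n_a + n_b - 2`), matching
#' the pooled-SD conventions used throughout this analysis; set
#' `var_equal = FALSE` for Welch's unequal-variance form.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @param alpha_adjusted Significance threshold recorded in the result.
#' @return One-row tibble as in [paired_t()].
#' @export
independent_t <- function(a, b, var_equal = TRUE, alpha_adjusted = 0.05) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) {
    stop("unpaired t-test requires n >= 2 in both groups", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (se == 0) {
    if (diff == 0) return(t_result(0, df, 1, alpha_adjusted))
    return(t_result(sign(diff) * Inf, df, 0, alpha_adjusted, degenerate = TRUE))
  }
  stat <- diff / se
  t_result(stat, df, 2 * stats::pt(-abs(stat), df), alpha_adjusted)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param k Number of tests (>= 1).
#' @return `alpha / k`. For the six t-tests of the pre/post design,
#'   `bonferroni_alpha(0.05, 6)` is 0.00833..., printed as 0.008.
#' @export
bonferroni_alpha <- function(alpha, k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  alpha / k
}

#' Qualitative band for a Cohen's d
#'
#' Bands on |d| with contiguous half-open intervals: `[0, 0.2)` trivial,
#' `[0.2, 0.5)` small, `[0.5, 0.8)` moderate, `[0.8, 1.2)` large, `[1.2, 2]`
#' very large, `> 2` huge.
#'
#' @param d Numeric vector of effect sizes (sign ignored).
#' @return Character vector of band labels.
#' @examples
#' classify_effect(c(0.23, 0.79, 1.12, 2.59))
#' @export
classify_effect <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a < 0.2 ~ "trivial",
    a < 0.5 ~ "small",
    a < 0.8 ~ "moderate",
    a < 1.2 ~ "large",
    a <= 2.0 ~ "very large",
    TRUE ~ "huge"
  )
}

#' Within-group Cohen's d from pre/post summaries
#'
#' `d = (mean_post - mean_pre) / sqrt((sd_pre^2 + sd_post^2) / 2)` -- the
#' root-mean-square of the two time-point SDs as denominator, the convention
#' that reproduces published pre/post effect sizes from summary tables.
#'
#' @param mean_pre,sd_pre,mean_post,sd_post Time-point summaries (SDs >= 0,
#'   not both zero).
#' @return One-row tibble: `d`, `band`.
#' @examples
#' cohen_d_prepost(1006, 292, 1073, 281)  # d ~ 0.23, "small"
#' @export
cohen_d_prepost <- function(mean_pre, sd_pre, mean_post, sd_post) {
  if (sd_pre < 0 || sd_post < 0) stop("SDs must be non-negative", call. = FALSE)
  denom <- sqrt((sd_pre^2 + sd_post^2) / 2)
  if (denom == 0) {
    stop("effect size undefined: both SDs are zero", call. = FALSE)
  }
  d <- (mean_post - mean_pre) / denom
  tibble::tibble(d = d, band = classify_effect(d))
}

#' Between-group Cohen's d from group summaries
#'
#' `d = |mean2 - mean1| / s_pooled` with the (n-1)-weighted pooled SD
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1 First group's mean, SD and size (n >= 2).
#' @param mean2,sd2,n2 Second group's.
#' @return One-row tibble: `d` (non-negative), `band`.
#' @examples
#' cohen_d_independent(67, 33, 6, 364, 248, 23)  # d ~ 1.32, "very large"
#' @export
cohen_d_independent <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("both groups need n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean1 == mean2) return(tibble::tibble(d = 0, band = "trivial"))
    stop("effect size undefined: pooled variance is zero", call. = FALSE)
  }
  d <- abs(mean2 - mean1) / sqrt(sp2)
  tibble::tibble(d = d, band = classify_effect(d))
}

#' Percent improvement as a ratio of group means
#'
#' `100 * mean_improvement / mean_pre`. This is the convention behind
#' headline "the high group improved 58%"-style figures; contrast with
#' [mean_individual_percent_improvement()], which averages each subject's own
#' percentage and generally gives a different number.
#'
#' @param mean_improvement Group mean improvement (m).
#' @param mean_pre Group mean pre-training distance (m, > 0).
#' @return Percent (0--100 scale, unrounded).
#' @export
percent_improvement_of_means <- function(mean_improvement, mean_pre) {
  if (mean_pre <= 0) stop("mean_pre must be > 0", call. = FALSE)
  100 * mean_improvement / mean_pre
}

#' Mean of individual percent improvements
#'
#' Averages `100 * (post - pre) / pre` over subjects. Requires raw data and
#' every pre-training distance positive.
#'
#' @param subjects Tibble with `pre_yoyo_m` and `post_yoyo_m` columns.
#' @return Percent (unrounded).
#' @export
mean_individual_percent_improvement <- function(subjects) {
  pre <- subjects$pre_yoyo_m; post <- subjects$post_yoyo_m
  if (any(pre <= 0)) {
    stop("individual percent improvement undefined for pre_yoyo_m <= 0",
         call. = FALSE)
  }
  mean(100 * (post - pre) / pre)
}

#' Count responders above improvement thresholds
#'
#' For each threshold, counts improvements strictly greater than it. The
#' shipped defaults are the 120 m meaningful-change and 500 m
#' large-responder cut-offs.
#'
#' @param improvements Numeric vector of improvements (m).
#' @param thresholds Numeric vector of cut-offs (m), non-empty.
#' @return Tibble: `threshold`, `count`, `n`, `proportion`.
#' @examples
#' responder_counts(c(100, 130, 600), thresholds = c(120, 500))
#' @export
responder_counts <- function(improvements, thresholds = c(120, 500)) {
  if (!length(thresholds)) stop("thresholds must be non-empty", call. = FALSE)
  n_subj <- length(improvements)
  counts <- vapply(thresholds, function(th) sum(improvements > th), integer(1))
  tibble::tibble(
    threshold = as.numeric(thresholds),
    count = counts,
    n = n_subj,
    proportion = if (n_subj == 0) NA_real_ else counts / n_subj
  )
}
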