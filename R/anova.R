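# 3x2 (Group x Time) split-plot ANOVA with repeated measures on time, and
# Tukey's HSD follow-up. With exactly two within-subject levels the
# within-subject tests are exact functions of per-subject difference scores:
# the interaction is a one-way ANOVA on differences and the time effect tests
# the difference grand mean. Unbalanced groups are handled by Type III
# (unweighted means over an harmonic-mean group size, the SPSS-style default)
# or by a sums-over-observations weighted variant.

anova_table <- function(effects, type, partial = FALSE, ns = NULL) {
  structure(
    list(table = effects, type = type, partial = partial, ns = ns),
    class = "split_plot_anova"
  )
}

#' @export
print.split_plot_anova <- function(x, ...) {
  cat("Split-plot (Group x Time) ANOVA, ", x$type, " sums of squares",
      if (x$partial) " [partial: summaries only, no between-subjects effect]",
      "\n", sep = "")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname split_plot_anova
#' @param x A `split_plot_anova` object.
#' @param ... Unused.
#' @method tidy split_plot_anova
#' @export
tidy.split_plot_anova <- function(x, ...) x$table

#' @rdname split_plot_anova
#' @method glance split_plot_anova
#' @export
glance.split_plot_anova <- function(x, ...) {
  tab <- x$table
  grab <- function(eff, col) {
    v <- tab[[col]][tab$effect == eff]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    type = x$type, partial = x$partial,
    f_group = grab("group", "statistic"), p_group = grab("group", "p_value"),
    f_time = grab("time", "statistic"), p_time = grab("time", "p_value"),
    f_interaction = grab("group:time", "statistic"),
    p_interaction = grab("group:time", "p_value")
  )
}

split_plot_from_stats <- function(mean_d, var_d, mean_s, var_s, ns, type) {
  k <- length(ns)
  N <- sum(ns)
  n_h <- k / sum(1 / ns)
  if (type == "III") {
    dbar <- mean(mean_d)
    ss_time <- k * n_h * dbar^2 / 2
    ss_int <- n_h * sum((mean_d - dbar)^2) / 2
    ss_group <- if (is.null(mean_s)) NA_real_ else {
      2 * n_h * sum((mean_s - mean(mean_s))^2)
    }
  } else {
    dbar <- sum(ns * mean_d) / N
    ss_time <- N * dbar^2 / 2
    ss_int <- sum(ns * (mean_d - dbar)^2) / 2
    ss_group <- if (is.null(mean_s)) NA_real_ else {
      sbar <- sum(ns * mean_s) / N
      2 * sum(ns * (mean_s - sbar)^2)
    }
  }
  ss_werr <- sum((ns - 1) * var_d) / 2
  df_err <- N - k
  ms_werr <- ss_werr / df_err
  # an effect with zero SS is reported as F = 0 even when the error MS is
  # also zero (all-identical responses)
  safe_f <- function(ms_eff, ms_err) {
    if (ms_eff == 0) 0 else ms_eff / ms_err
  }
  f_time <- safe_f(ss_time, ms_werr)
  rows <- list(
    tibble::tibble(effect = "time", ss = ss_time, df = 1, ms = ss_time,
                   statistic = f_time,
                   p_value = stats::pf(f_time, 1, df_err, lower.tail = FALSE))
  )
  if (k >= 2) {
    ms_int <- ss_int / (k - 1)
    f_int <- safe_f(ms_int, ms_werr)
    rows <- c(rows, list(
      tibble::tibble(effect = "group:time", ss = ss_int, df = k - 1,
                     ms = ms_int, statistic = f_int,
                     p_value = stats::pf(f_int, k - 1, df_err,
                                         lower.tail = FALSE))
    ))
  }
  if (!is.null(mean_s)) {
    ss_berr <- 2 * sum((ns - 1) * var_s)
    ms_berr <- ss_berr / df_err
    ms_group <- ss_group / (k - 1)
    f_group <- safe_f(ms_group, ms_berr)
    rows <- c(
      list(tibble::tibble(
        effect = "group", ss = ss_group, df = k - 1, ms = ms_group,
        statistic = f_group,
        p_value = stats::pf(f_group, k - 1, df_err, lower.tail = FALSE)
      ),
      tibble::tibble(effect = "subjects within groups", ss = ss_berr,
                     df = df_err, ms = ms_berr,
                     statistic = NA_real_, p_value = NA_real_)),
      rows,
      list(tibble::tibble(effect = "time x subjects within groups",
                          ss = ss_werr, df = df_err, ms = ms_werr,
                          statistic = NA_real_, p_value = NA_real_))
    )
  } else {
    rows <- c(rows, list(tibble::tibble(
      effect = "time x subjects within groups", ss = ss_werr, df = df_err,
      ms = ms_werr, statistic = NA_real_, p_value = NA_real_
    )))
  }
  dplyr::bind_rows(rows)
}

#' Split-plot ANOVA for a pre/post design with a grouping factor
#'
#' Classical univariate mixed-model decomposition for one between-subjects
#' factor and a two-level within-subjects factor (time). The group effect is
#' tested against the between-subjects error, time and the Group x Time
#' interaction against the within-subjects error; degrees of freedom sum to
#' `2N - 1`. With two time levels sphericity holds trivially, so no
#' correction is applied.
#'
#' @param data Tibble with one row per subject.
#' @param group,pre,post Names of the grouping and the two time-point columns.
#' @param type `"III"` (unweighted means, harmonic group size; the default,
#'   appropriate for unbalanced strata) or `"weighted"` (sums over
#'   observations). The two coincide on balanced designs.
#' @return A `split_plot_anova` object; `tidy()` returns the ANOVA table with
#'   columns `effect`, `ss`, `df`, `ms`, `statistic`, `p_value`.
#' @export
split_plot_anova <- function(data, group = "stratum", pre = "pre_yoyo_m",
                             post = "post_yoyo_m",
                             type = c("III", "weighted")) {
  type <- match.arg(type)
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  pre_v <- as.numeric(data[[pre]]); post_v <- as.numeric(data[[post]])
  if (anyNA(pre_v) || anyNA(post_v)) stop("missing measurements", call. = FALSE)
  d <- post_v - pre_v
  s <- (pre_v + post_v) / 2
  ns <- as.integer(table(g))
  if (any(ns < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  out <- split_plot_from_stats(
    mean_d = tapply(d, g, mean), var_d = tapply(d, g, stats::var),
    mean_s = tapply(s, g, mean), var_s = tapply(s, g, stats::var),
    ns = ns, type = type
  )
  anova_table(out, type = type, partial = FALSE,
              ns = stats::setNames(ns, levels(g)))
}

#' Time and interaction tests from printed difference-score summaries
#'
#' With exactly two within-subject levels, the time main effect and the
#' Group x Time interaction of the split-plot ANOVA depend only on the
#' per-group mean, SD and size of the difference scores (post - pre), so a
#' published table suffices to recompute them. The between-subjects (group)
#' effect additionally needs the pre/post correlation and is not returned:
#' the result is flagged `partial`.
#'
#' @param diff_means,diff_sds,ns Equal-length vectors of per-group difference
#'   means (m), SDs (m) and sizes (each n >= 2).
#' @param type As in [split_plot_anova()].
#' @return A partial `split_plot_anova` with `time`, `group:time` and the
#'   within-subjects error term. With one group the interaction is undefined
#'   and only the time row (the squared one-sample t) is returned.
#' @examples
#' # the study's printed per-stratum improvement summaries
#' tidy(anova_from_summaries(c(67, 364, 560), c(33, 248, 225), c(6, 23, 13)))
#' @export
anova_from_summaries <- function(diff_means, diff_sds, ns,
                                 type = c("III", "weighted")) {
  type <- match.arg(type)
  if (length(diff_means) != length(diff_sds) ||
      length(diff_means) != length(ns)) {
    stop("diff_means, diff_sds and ns must have equal length", call. = FALSE)
  }
  if (any(ns < 2)) stop("every group needs n >= 2", call. = FALSE)
  k <- length(ns)
  out <- split_plot_from_stats(
    mean_d = as.numeric(diff_means), var_d = as.numeric(diff_sds)^2,
    mean_s = NULL, var_s = NULL, ns = as.numeric(ns), type = type
  )
  if (k == 1L) out <- out[out$effect != "group:time", ]
  anova_table(out, type = type, partial = TRUE, ns = as.integer(ns))
}

#' Tukey's HSD (Tukey--Kramer) pairwise comparisons
#'
#' All pairwise group comparisons via the studentized-range distribution:
#' `q_ij = |mean_i - mean_j| / sqrt(mse/2 * (1/n_i + 1/n_j))` (Kramer's form
#' for unequal n), with adjusted p from `ptukey(q, k, df_error)`. By default
#' `mse` is the one-way pooled within-group variance of the supplied values
#' and `df_error = N - k`; pass `mse`/`df_error` explicitly to follow up a
#' different error term (e.g. the between-subjects error of a split-plot
#' ANOVA).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param mse Error mean square on the scale of the supplied values; default
#'   pooled within-group variance.
#' @param df_error Error degrees of freedom; default `N - k`.
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean2 - mean1), `q`, `adj_p_value`.
#' @export
tukey_hsd <- function(values_by_group, mse = NULL, df_error = NULL) {
  k <- length(values_by_group)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(values_by_group))) {
    names(values_by_group) <- paste0("group", seq_len(k))
  }
  ns <- lengths(values_by_group)
  means <- vapply(values_by_group, mean, numeric(1))
  if (is.null(mse)) {
    if (any(ns < 2L)) {
      stop("pooled MSE needs n >= 2 per group (or pass mse explicitly)",
           call. = FALSE)
    }
    vars <- vapply(values_by_group, stats::var, numeric(1))
    mse <- sum((ns - 1) * vars) / (sum(ns) - k)
    if (is.null(df_error)) df_error <- sum(ns) - k
  }
  if (is.null(df_error)) stop("df_error required when mse is supplied",
                              call. = FALSE)
  if (mse <= 0) stop("MSE must be > 0", call. = FALSE)
  pairs <- utils::combn(names(values_by_group), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[[i1]] + 1 / ns[[i2]]))
    q <- abs(means[[i2]] - means[[i1]]) / se
    tibble::tibble(
      group1 = i1, group2 = i2, diff = means[[i2]] - means[[i1]], q = q,
      adj_p_value = stats::ptukey(q, nmeans = k, df = df_error,
                                  lower.tail = FALSE)
    )
  })
}
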