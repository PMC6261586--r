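# Orchestration: score -> stratify -> analyse -> report. run_analysis()
# computes every statistic of the pre/post design; render_report() owns all
# rounding ("mean (SD; CI)" cells to whole metres, d to 2 decimals, percent
# to 1 decimal) so the statistical layer stays unrounded.

STRATA <- c("low", "medium", "high")

#' Full genotype-stratified pre/post analysis
#'
#' Runs the complete analysis of a genotyped pre/post cohort: per-stratum and
#' whole-cohort summaries (mean, SD, t-interval) for pre, post and
#' improvement; paired t-tests within strata and pooled-variance unpaired
#' t-tests between strata on improvements, all against a Bonferroni-adjusted
#' threshold (alpha / number of t-tests); within-stratum Cohen's d (RMS of the
#' pre/post SDs) and between-stratum d (pooled SD), each with its qualitative
#' band; the Group x Time split-plot ANOVA with Tukey's HSD follow-up on
#' subject means; responder counts at the configured thresholds; and both
#' percent-improvement conventions. Inferential blocks degrade gracefully:
#' strata with fewer than two subjects are summarised but not tested, and the
#' ANOVA/Tukey block is skipped (with a note) when fewer than two strata are
#' testable.
#'
#' @param subjects Subject tibble (from [read_subject_table()] or
#'   [simulate_cohort()]). If `percent`/`stratum` are absent they are computed
#'   with [tgs_score()].
#' @param panel A `tgs_panel`.
#' @param conf_level Confidence level for all intervals (default 0.90).
#' @param alpha Family-wise significance level (default 0.05).
#' @param thresholds Responder improvement cut-offs in metres.
#' @param anova_type `"III"` or `"weighted"`, see [split_plot_anova()].
#' @param ttest `"pooled"` (Student) or `"welch"` for the between-group tests.
#' @return A `trainability_report` object (a list of tibbles; see
#'   [render_report()], [tidy()] and [glance()]).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_subjects = 42, seed = 11))
#' report <- run_analysis(cohort)
#' glance(report)
#' @export
run_analysis <- function(subjects, panel = default_panel(), conf_level = 0.90,
                         alpha = 0.05, thresholds = c(120, 500),
                         anova_type = c("III", "weighted"),
                         ttest = c("pooled", "welch")) {
  anova_type <- match.arg(anova_type)
  ttest <- match.arg(ttest)
  if (nrow(subjects) == 0L) stop("empty cohort", call. = FALSE)
  if (!"stratum" %in% names(subjects)) {
    subjects <- tgs_score(subjects, panel)
  }
  if (!"percent" %in% names(subjects)) subjects$percent <- NA_real_
  subjects$stratum <- factor(subjects$stratum, levels = STRATA)
  subjects$improvement_m <- subjects$post_yoyo_m - subjects$pre_yoyo_m

  occupied <- STRATA[STRATA %in% subjects$stratum]
  by_stratum <- split(subjects, subjects$stratum, drop = FALSE)[occupied]
  ns <- vapply(by_stratum, nrow, integer(1))
  testable <- names(ns)[ns >= 2]
  n_tests <- length(testable) + choose(length(testable), 2)
  alpha_adj <- if (n_tests >= 1) bonferroni_alpha(alpha, n_tests) else alpha

  summarise_block <- function(df, label) {
    purrr::map_dfr(
      c(pre = "pre_yoyo_m", post = "post_yoyo_m",
        improvement = "improvement_m"),
      function(col) {
        v <- df[[col]]
        if (length(v) >= 2) {
          group_summary(v, conf_level, label)
        } else {
          tibble::tibble(label = label, n = length(v), mean = mean(v),
                         sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                         conf_level = conf_level)
        }
      },
      .id = "period"
    )
  }
  summaries <- dplyr::bind_rows(
    purrr::imap_dfr(by_stratum, summarise_block),
    summarise_block(subjects, "all")
  )
  summaries <- summaries[, c("label", "period", "n", "mean", "sd",
                             "ci_low", "ci_high", "conf_level")]

  paired_tests <- purrr::imap_dfr(by_stratum, function(df, label) {
    if (nrow(df) >= 2) {
      dplyr::bind_cols(tibble::tibble(stratum = label),
                       paired_t(df$pre_yoyo_m, df$post_yoyo_m, alpha_adj))
    } else {
      tibble::tibble(stratum = label, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, alpha_adjusted = alpha_adj,
                     degenerate = NA)
    }
  })

  within_effects <- purrr::imap_dfr(by_stratum, function(df, label) {
    if (nrow(df) < 2) {
      return(tibble::tibble(stratum = label, d = NA_real_,
                            band = NA_character_))
    }
    es <- cohen_d_prepost(mean(df$pre_yoyo_m), stats::sd(df$pre_yoyo_m),
                          mean(df$post_yoyo_m), stats::sd(df$post_yoyo_m))
    dplyr::bind_cols(tibble::tibble(stratum = label), es)
  })

  pair_rows <- if (length(testable) >= 2) utils::combn(testable, 2) else NULL
  between_tests <- between_effects <- NULL
  if (!is.null(pair_rows)) {
    between_tests <- purrr::map_dfr(seq_len(ncol(pair_rows)), function(j) {
      g1 <- pair_rows[1, j]; g2 <- pair_rows[2, j]
      tt <- independent_t(by_stratum[[g1]]$improvement_m,
                          by_stratum[[g2]]$improvement_m,
                          var_equal = ttest == "pooled",
                          alpha_adjusted = alpha_adj)
      dplyr::bind_cols(tibble::tibble(group1 = g1, group2 = g2), tt)
    })
    between_effects <- purrr::map_dfr(seq_len(ncol(pair_rows)), function(j) {
      g1 <- pair_rows[1, j]; g2 <- pair_rows[2, j]
      a <- by_stratum[[g1]]$improvement_m; b <- by_stratum[[g2]]$improvement_m
      es <- cohen_d_independent(mean(a), stats::sd(a), length(a),
                                mean(b), stats::sd(b), length(b))
      dplyr::bind_cols(tibble::tibble(group1 = g1, group2 = g2), es)
    })
  }

  anova <- tukey <- NULL
  anova_note <- NULL
  if (length(testable) >= 2) {
    testable_df <- subjects[subjects$stratum %in% testable, ]
    testable_df$stratum <- droplevels(testable_df$stratum)
    anova <- split_plot_anova(testable_df, type = anova_type)
    subj_means <- split((testable_df$pre_yoyo_m + testable_df$post_yoyo_m) / 2,
                        testable_df$stratum)
    tukey <- tukey_hsd(subj_means)
  } else {
    anova_note <- "not computable: fewer than 2 strata with n >= 2"
  }

  responders <- dplyr::bind_rows(
    purrr::imap_dfr(by_stratum, function(df, label) {
      dplyr::bind_cols(tibble::tibble(stratum = label),
                       responder_counts(df$improvement_m, thresholds))
    }),
    dplyr::bind_cols(tibble::tibble(stratum = "all"),
                     responder_counts(subjects$improvement_m, thresholds))
  )

  pct_block <- function(df, label) {
    tibble::tibble(
      label = label,
      ratio_of_means = if (mean(df$pre_yoyo_m) > 0)
        percent_improvement_of_means(mean(df$improvement_m),
                                     mean(df$pre_yoyo_m)) else NA_real_,
      mean_individual = if (all(df$pre_yoyo_m > 0))
        mean_individual_percent_improvement(df) else NA_real_
    )
  }
  percent_improvements <- dplyr::bind_rows(
    purrr::imap_dfr(by_stratum, pct_block),
    pct_block(subjects, "all")
  )

  per_subject <- subjects[order(subjects$stratum, -subjects$improvement_m), ]
  per_subject <- tibble::tibble(
    id = per_subject$id, stratum = as.character(per_subject$stratum),
    percent = per_subject$percent,
    pre_yoyo_m = per_subject$pre_yoyo_m,
    post_yoyo_m = per_subject$post_yoyo_m,
    improvement_m = per_subject$improvement_m,
    pct_improvement = ifelse(per_subject$pre_yoyo_m > 0,
                             100 * per_subject$improvement_m /
                               per_subject$pre_yoyo_m, NA_real_)
  )

  structure(
    list(
      meta = tibble::tibble(
        n = nrow(subjects), n_strata = length(occupied),
        conf_level = conf_level, alpha = alpha, n_t_tests = n_tests,
        alpha_adjusted = alpha_adj, anova_type = anova_type, ttest = ttest
      ),
      strata_n = tibble::tibble(stratum = names(ns), n = unname(ns)),
      summaries = summaries,
      paired_tests = paired_tests,
      within_effects = within_effects,
      between_tests = between_tests,
      between_effects = between_effects,
      anova = anova, anova_note = anova_note, tukey = tukey,
      responders = responders,
      percent_improvements = percent_improvements,
      per_subject = per_subject
    ),
    class = "trainability_report"
  )
}

#' @export
print.trainability_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

#' @rdname run_analysis
#' @param x A `trainability_report`.
#' @param ... Unused.
#' @method tidy trainability_report
#' @export
tidy.trainability_report <- function(x, ...) x$summaries

#' @rdname run_analysis
#' @method glance trainability_report
#' @export
glance.trainability_report <- function(x, ...) {
  g <- x$meta
  if (!is.null(x$anova)) {
    a <- glance(x$anova)
    g$f_time <- a$f_time
    g$p_time <- a$p_time
    g$f_interaction <- a$f_interaction
    g$p_interaction <- a$p_interaction
  }
  g
}

fmt_m <- function(x) ifelse(is.na(x), "NA", sprintf("%.0f", x))
fmt_d <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
fmt_pct <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p)))
}
fmt_cell <- function(mean, sd, lo, hi) {
  ifelse(is.na(sd), fmt_m(mean),
         sprintf("%s (%s; %s to %s)", fmt_m(mean), fmt_m(sd),
                 fmt_m(lo), fmt_m(hi)))
}

report_text <- function(x) {
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  m <- x$meta
  push("Genotype-stratified training-response report")
  push(sprintf("n = %d subjects in %d strata (%s)", m$n, m$n_strata,
               paste(sprintf("%s=%d", x$strata_n$stratum, x$strata_n$n),
                     collapse = ", ")))
  push(sprintf(
    "conventions: %s unpaired t, type %s ANOVA, %.0f%% CI, alpha %s (%d t-tests, Bonferroni-adjusted %.3f)",
    m$ttest, m$anova_type, 100 * m$conf_level,
    format(m$alpha), m$n_t_tests, m$alpha_adjusted))
  small <- x$strata_n$stratum[x$strata_n$n < 10]
  if (length(small)) {
    push("note: stratum n < 10 for ", paste(small, collapse = ", "),
         "; interpret stratum inference cautiously")
  }
  push("")
  push("Pre/post Yo-Yo distance by stratum [mean (SD; CI)]")
  wide <- tidyr::pivot_wider(
    x$summaries,
    id_cols = "label", names_from = "period",
    values_from = c("n", "mean", "sd", "ci_low", "ci_high")
  )
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    p <- x$paired_tests[x$paired_tests$stratum == w$label, ]
    e <- x$within_effects[x$within_effects$stratum == w$label, ]
    push(sprintf(
      "  %-7s (n = %d)  pre %s   post %s   p %s   d %s%s",
      w$label, w$n_pre,
      fmt_cell(w$mean_pre, w$sd_pre, w$ci_low_pre, w$ci_high_pre),
      fmt_cell(w$mean_post, w$sd_post, w$ci_low_post, w$ci_high_post),
      if (nrow(p)) fmt_p(p$p_value) else "NA",
      if (nrow(e)) fmt_d(e$d) else "NA",
      if (nrow(e) && !is.na(e$band)) sprintf(" \"%s\"", e$band) else ""
    ))
  }
  push("")
  push("Improvement by stratum [mean (SD; CI)]; percent by both conventions")
  for (i in seq_len(nrow(wide))) {
    w <- wide[i, ]
    pc <- x$percent_improvements[x$percent_improvements$label == w$label, ]
    push(sprintf(
      "  %-7s %s   ratio-of-means %s%%   mean-individual %s%%",
      w$label,
      fmt_cell(w$mean_improvement, w$sd_improvement,
               w$ci_low_improvement, w$ci_high_improvement),
      fmt_pct(pc$ratio_of_means), fmt_pct(pc$mean_individual)
    ))
  }
  if (!is.null(x$between_tests)) {
    push("")
    push(sprintf("Between-stratum improvement comparisons (adjusted alpha %.3f)",
                 m$alpha_adjusted))
    for (i in seq_len(nrow(x$between_tests))) {
      bt <- x$between_tests[i, ]
      be <- x$between_effects[i, ]
      push(sprintf("  %s vs %s: t = %s, p %s, d = %s \"%s\"",
                   bt$group1, bt$group2, fmt_d(bt$statistic),
                   fmt_p(bt$p_value), fmt_d(be$d), be$band))
    }
  }
  push("")
  if (!is.null(x$anova)) {
    tab <- x$anova$table
    push(sprintf("Split-plot ANOVA (type %s)", x$anova$type))
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      if (is.na(r$statistic)) {
        push(sprintf("  %-28s SS %s  df %d  MS %s", r$effect, fmt_m(r$ss),
                     as.integer(r$df), fmt_m(r$ms)))
      } else {
        push(sprintf("  %-28s F(%d, %d) = %s, p %s", r$effect,
                     as.integer(r$df),
                     as.integer(tab$df[tab$effect ==
                       if (r$effect == "group") "subjects within groups"
                       else "time x subjects within groups"]),
                     sprintf("%.1f", r$statistic), fmt_p(r$p_value)))
      }
    }
    push("Tukey HSD on subject means:")
    for (i in seq_len(nrow(x$tukey))) {
      tk <- x$tukey[i, ]
      push(sprintf("  %s vs %s: diff %s m, q = %s, adj p %s", tk$group1,
                   tk$group2, fmt_m(tk$diff), fmt_d(tk$q),
                   fmt_p(tk$adj_p_value)))
    }
  } else if (!is.null(x$anova_note)) {
    push("Split-plot ANOVA ", x$anova_note)
  }
  push("")
  push("Responder counts (improvement strictly greater than threshold)")
  for (i in seq_len(nrow(x$responders))) {
    r <- x$responders[i, ]
    push(sprintf("  %-7s > %s m: %d/%d", r$stratum, fmt_m(r$threshold),
                 r$count, r$n))
  }
  out
}

report_blocks <- function(x) {
  blocks <- list(
    meta = x$meta, strata_n = x$strata_n, summaries = x$summaries,
    paired_tests = x$paired_tests, within_effects = x$within_effects,
    between_tests = x$between_tests, between_effects = x$between_effects,
    anova = if (!is.null(x$anova)) x$anova$table else NULL,
    tukey = x$tukey, responders = x$responders,
    percent_improvements = x$percent_improvements,
    per_subject = x$per_subject
  )
  blocks[!vapply(blocks, is.null, logical(1))]
}

#' Render an analysis report
#'
#' `"text"` mirrors the published table layout -- per-stratum
#' "mean (SD; CI to CI)" cells with the paired p and banded d -- with
#' distances rounded to whole metres, d to 2 decimals and percentages to 1
#' decimal. `"tsv"` emits every result block as a tab-separated section and
#' `"json"` a single JSON document at full representation precision.
#' Rendering the same report twice is byte-identical.
#'
#' @param report A `trainability_report`.
#' @param format One of `"text"`, `"tsv"`, `"json"`.
#' @return A character vector of lines (`text`, `tsv`) or a JSON string.
#' @export
render_report <- function(report, format = c("text", "tsv", "json")) {
  stopifnot(inherits(report, "trainability_report"))
  format <- match.arg(format)
  if (format == "text") return(report_text(report))
  blocks <- report_blocks(report)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(blocks, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA,
                                         na = "null", pretty = TRUE)))
  }
  out <- character(0)
  for (nm in names(blocks)) {
    df <- as.data.frame(blocks[[nm]])
    out <- c(out, paste0("# ", nm),
             paste(names(df), collapse = "\t"),
             apply(df, 1, function(r) paste(trimws(r), collapse = "\t")), "")
  }
  out
}

#' Per-subject improvement chart
#'
#' Bar chart of each subject's percent improvement, ordered within stratum --
#' the individual-response view that makes trainability heterogeneity
#' visible.
#'
#' @param report A `trainability_report`.
#' @return A ggplot object.
#' @export
plot_individual_improvements <- function(report) {
  df <- report$per_subject
  df$id <- factor(df$id, levels = df$id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$pct_improvement,
                                   fill = .data$stratum)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Improvement (% of pre-training distance)",
                  fill = "TGS stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Group mean improvements with confidence intervals
#'
#' @param report A `trainability_report`.
#' @return A ggplot object.
#' @export
plot_group_improvements <- function(report) {
  df <- report$summaries
  df <- df[df$period == "improvement" & df$label != "all", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = "TGS stratum", y = "Mean improvement (m)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_individual_improvements
#' @param object A `trainability_report`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot trainability_report
#' @export
autoplot.trainability_report <- function(object, ...) {
  plot_individual_improvements(object)
}
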