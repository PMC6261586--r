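# Synthetic cohorts with the study's statistical structure: Hardy-Weinberg
# genotypes at the panel SNPs and a training response linear in the TGS
# percentage. The generator's defaults emulate a ~42-player youth-soccer
# squad doing eight weeks of aerobic training: baseline Yo-Yo IR1 distance
# ~1015 +/- 450 m and an improvement of (-335 + 11.5 * TGS%) +/- 225 m, a
# back-of-envelope linear fit to the published stratum summaries (invented
# calibration, not measured constants).

#' Simulation configuration for a synthetic cohort
#'
#' @param n_subjects Cohort size (>= 1); default 42.
#' @param seed Integer seed; the same config + seed reproduces the cohort
#'   exactly.
#' @param panel A `tgs_panel`; default [default_panel()].
#' @param effect_allele_freqs Named vector of effect-allele frequencies, one
#'   per panel rsid, each in `[0, 1]`. The default 0.5 at every SNP puts
#'   roughly 60% of subjects in the medium stratum under the 0/2/4 weights
#'   (heterozygote-heavy binomial mass between the 40% and 70% cut-offs).
#' @param baseline_mean,baseline_sd Pre-training Yo-Yo distance model (m);
#'   normal, truncated at 0.
#' @param response_intercept,response_slope Improvement model (m and m per
#'   TGS-percent): `improvement = intercept + slope * percent + noise`.
#' @param response_noise_sd SD of the Gaussian improvement noise (m).
#' @param round_to_shuttle Round distances to the nearest 40 m shuttle
#'   (off by default so statistical checks see continuous data).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 42,
                              seed = 1L,
                              panel = default_panel(),
                              effect_allele_freqs = NULL,
                              baseline_mean = 1015,
                              baseline_sd = 450,
                              response_intercept = -335,
                              response_slope = 11.5,
                              response_noise_sd = 225,
                              round_to_shuttle = FALSE) {
  stopifnot(inherits(panel, "tgs_panel"))
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (baseline_sd < 0 || response_noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (is.null(effect_allele_freqs)) {
    effect_allele_freqs <- stats::setNames(rep(0.5, nrow(panel)), panel$rsid)
  }
  missing <- setdiff(panel$rsid, names(effect_allele_freqs))
  if (length(missing)) {
    stop("effect_allele_freqs lacks panel rsid(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(effect_allele_freqs < 0) || any(effect_allele_freqs > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      panel = panel,
      effect_allele_freqs = effect_allele_freqs[panel$rsid],
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      response_intercept = response_intercept,
      response_slope = response_slope,
      response_noise_sd = response_noise_sd,
      round_to_shuttle = isTRUE(round_to_shuttle)
    ),
    class = "simulation_config"
  )
}

# zero-truncated normal by rejection; keeps pre-training distances strictly
# positive so per-subject percent improvements stay defined
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) {
    if (mean <= 0) stop("degenerate baseline at or below 0 m", call. = FALSE)
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

genotype_strings <- function(effect, other) {
  c(paste0(other, other),
    paste0(min(effect, other), max(effect, other)),
    paste0(effect, effect))
}

#' Draw Hardy-Weinberg genotypes for a cohort
#'
#' Per SNP, genotypes carry 2/1/0 effect alleles with probabilities `p^2`,
#' `2p(1-p)`, `(1-p)^2`, independently across SNPs and subjects (no linkage
#' disequilibrium).
#'
#' @param config A [simulation_config()].
#' @return Tibble: `id` plus one genotype column per panel rsid.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  simulate_genotypes_impl(config)
}

simulate_genotypes_impl <- function(config) {
  panel <- config$panel
  n <- config$n_subjects
  out <- tibble::tibble(id = sprintf("S%03d", seq_len(n)))
  for (i in seq_len(nrow(panel))) {
    p <- config$effect_allele_freqs[[panel$rsid[i]]]
    copies <- stats::rbinom(n, size = 2, prob = p)
    keys <- genotype_strings(panel$effect_allele[i], panel$other_allele[i])
    out[[panel$rsid[i]]] <- keys[copies + 1L]
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws HWE genotypes, scores them, then generates
#' `pre ~ N(baseline_mean, baseline_sd)` truncated at 0 and
#' `improvement = intercept + slope * TGS% + N(0, noise_sd)`; the
#' post-training distance is `pre + improvement`, floored at 0 m. Negative
#' improvements are permitted (real squads contain decrementers); only
#' physically impossible negative distances are clipped. With
#' `round_to_shuttle` both distances snap to the 40 m Yo-Yo quantum.
#'
#' @param config A [simulation_config()].
#' @return Subject tibble compatible with [read_subject_table()] output:
#'   `id`, genotype columns, `pre_yoyo_m`, `post_yoyo_m`, plus the generating
#'   `percent` and `stratum` (recomputable via [tgs_score()]).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_subjects = 12, seed = 7))
#' dplyr::count(cohort, stratum)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  subjects <- simulate_genotypes_impl(config)
  scored <- tgs_score(subjects, config$panel)
  n <- config$n_subjects
  pre <- rnorm_trunc0(n, config$baseline_mean, config$baseline_sd)
  improvement <- config$response_intercept +
    config$response_slope * scored$percent +
    stats::rnorm(n, 0, config$response_noise_sd)
  post <- pmax(0, pre + improvement)
  if (config$round_to_shuttle) {
    pre <- 40 * round(pre / 40)
    post <- 40 * round(post / 40)
  }
  subjects$pre_yoyo_m <- pre
  subjects$post_yoyo_m <- post
  subjects$percent <- scored$percent
  subjects$stratum <- scored$stratum
  subjects
}

#' Recover the response slope from a cohort
#'
#' Ordinary least squares of improvement (post - pre) on the TGS percentage;
#' the parameter-recovery harness for the simulator's linear response model.
#'
#' @param subjects Subject tibble with genotypes and pre/post distances.
#' @param panel A `tgs_panel`.
#' @return One-row tibble: `estimate` (m per TGS-percent), `std_error`,
#'   `intercept`, `n`.
#' @export
recover_response_slope <- function(subjects, panel = default_panel()) {
  scored <- if ("percent" %in% names(subjects)) subjects else
    tgs_score(subjects, panel)
  if (nrow(scored) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (stats::var(scored$percent) == 0) {
    stop("TGS percent has zero variance; slope not identifiable", call. = FALSE)
  }
  fit <- stats::lm(I(post_yoyo_m - pre_yoyo_m) ~ percent, data = scored)
  cf <- summary(fit)$coefficients
  tibble::tibble(
    estimate = cf["percent", "Estimate"],
    std_error = cf["percent", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    n = nrow(scored)
  )
}
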