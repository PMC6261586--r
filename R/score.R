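# Total genotype score: per-SNP points, weighted percentage, stratification.

#' Score one genotype at one panel SNP
#'
#' @param genotype Two-character allele string (order-insensitive), with both
#'   alleles in the SNP's effect/other set.
#' @param snp One-row SNP definition (a row of a `tgs_panel`).
#' @return The points for that genotype (0, 1 or 2 effect-allele copies).
#' @examples
#' panel <- default_panel()
#' score_snp("CC", panel[panel$rsid == "rs2010963", ])  # 4
#' @export
score_snp <- function(genotype, snp) {
  genotype <- normalize_genotype(genotype)
  validate_genotype_alleles(genotype, snp, subject_id = "<direct>")
  n_effect <- sum(strsplit(genotype, "")[[1]] == snp$effect_allele)
  c(snp$points_0, snp$points_1, snp$points_2)[n_effect + 1L]
}

#' Assign the trainability stratum from a TGS percentage
#'
#' Strata partition the percent scale with half-open boundaries: `<= 40` is
#' `"low"`, `(40, 70]` is `"medium"`, `> 70` is `"high"`.
#'
#' @param percent Numeric vector of TGS percentages in `[0, 100]`.
#' @return Factor with levels `low`, `medium`, `high`.
#' @examples
#' stratify(c(40, 55, 70, 70.01))
#' @export
stratify <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0) || any(percent > 100)) {
    stop("TGS percent must lie in [0, 100]", call. = FALSE)
  }
  factor(
    ifelse(percent <= 40, "low", ifelse(percent <= 70, "medium", "high")),
    levels = c("low", "medium", "high")
  )
}

#' Total genotype score for a cohort
#'
#' Sums the per-SNP points over the panel, expresses the raw score as a
#' percentage of the panel maximum, and assigns the low/medium/high stratum.
#' In strict mode (the default) every panel rsid must be genotyped; with
#' `permissive = TRUE` subjects with missing genotypes are scored against the
#' attainable maximum of their non-missing SNPs (a rescaled denominator --
#' use deliberately, scores are then not strictly comparable across subjects).
#'
#' @param subjects Tibble with an `id` column and one genotype column per
#'   panel rsid (as returned by [read_subject_table()] or
#'   [simulate_cohort()]); other columns are carried along unchanged.
#' @param panel A `tgs_panel`; defaults to [default_panel()].
#' @param permissive Allow missing genotypes by rescaling the denominator.
#' @return The input tibble with `raw_points`, `percent` (0--100, full
#'   floating precision) and `stratum` columns appended.
#' @examples
#' cohort <- tibble::tibble(
#'   id = "S1", rs2010963 = "CC", rs1042713 = "GG", rs1042714 = "GG",
#'   rs1205 = "CC", rs8192678 = "GG", pre_yoyo_m = 1000, post_yoyo_m = 1400
#' )
#' tgs_score(cohort)
#' @export
tgs_score <- function(subjects, panel = default_panel(), permissive = FALSE) {
  stopifnot(inherits(panel, "tgs_panel"))
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  subjects <- tibble::as_tibble(subjects)
  missing_cols <- setdiff(panel$rsid, names(subjects))
  if (length(missing_cols) && !permissive) {
    stop("subjects lack genotype column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(subjects)
  raw <- numeric(n)
  denom <- numeric(n)
  for (i in seq_len(nrow(panel))) {
    rsid <- panel$rsid[i]
    g <- if (rsid %in% names(subjects)) {
      normalize_genotype(subjects[[rsid]])
    } else {
      rep(NA_character_, n)
    }
    missing <- is.na(g)
    if (any(missing) && !permissive) {
      stop("subject ", subjects$id[which(missing)[1]],
           " is missing a genotype at ", rsid,
           " (set permissive = TRUE to rescale the denominator)",
           call. = FALSE)
    }
    # canonical keys for 0/1/2 effect-allele copies, alphabetical within pair
    eff <- panel$effect_allele[i]; oth <- panel$other_allele[i]
    keys <- c(paste0(min(oth, oth), max(oth, oth)),
              paste0(min(eff, oth), max(eff, oth)),
              paste0(eff, eff))
    pts <- c(panel$points_0[i], panel$points_1[i], panel$points_2[i])
    idx <- match(g, keys)
    bad <- !missing & is.na(idx)
    if (any(bad)) {
      j <- which(bad)[1]
      stop("subject ", subjects$id[j], ", ", rsid, ": genotype ", g[j],
           " contains alleles outside {", eff, ",", oth, "}",
           " (no automatic strand flipping)", call. = FALSE)
    }
    scored <- !missing
    raw[scored] <- raw[scored] + pts[idx[scored]]
    denom[scored] <- denom[scored] + panel$points_2[i]
  }
  if (!permissive) denom <- rep(panel_max_points(panel), n)
  if (any(denom <= 0)) {
    stop("subject(s) with no scorable genotypes: ",
         paste(subjects$id[denom <= 0], collapse = ", "), call. = FALSE)
  }
  subjects$raw_points <- raw
  subjects$percent <- 100 * raw / denom
  subjects$stratum <- stratify(subjects$percent)
  subjects
}

#' Score a single genotype map against a panel
#'
#' Scalar convenience around [tgs_score()] for one subject held as a named
#' list/vector of genotypes.
#'
#' @param genotypes Named character vector or list, names are panel rsids.
#' @param panel A `tgs_panel`.
#' @param permissive Allow missing genotypes (rescaled denominator).
#' @return One-row tibble: `raw_points`, `percent`, `stratum`.
#' @export
total_genotype_score <- function(genotypes, panel = default_panel(),
                                 permissive = FALSE) {
  df <- tibble::as_tibble(as.list(unlist(genotypes)))
  df <- dplyr::bind_cols(tibble::tibble(id = "subject"), df)
  res <- tgs_score(df, panel, permissive = permissive)
  res[, c("raw_points", "percent", "stratum")]
}
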