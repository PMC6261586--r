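# Subject-table and VCF input. Genotypes are stored as two-character,
# alphabetically sorted allele strings ("CG", never "GC") so unordered pairs
# compare equal.

#' Normalise a two-allele genotype string
#'
#' Uppercases and sorts the two bases so that order-insensitive pairs ("CG",
#' "GC") map to one canonical key.
#'
#' @param genotype Character vector of two-character genotype strings.
#'   `NA` entries (missing genotypes) propagate unchanged.
#' @return Character vector of canonical genotype keys.
#' @examples
#' normalize_genotype(c("GC", "cg", "TT"))
#' @export
normalize_genotype <- function(genotype) {
  g <- toupper(genotype)
  bad <- !is.na(g) & nchar(g) != 2L
  if (any(bad)) {
    stop("genotype must be a two-character allele string, got: ",
         paste(unique(g[bad]), collapse = ", "), call. = FALSE)
  }
  a1 <- substr(g, 1, 1)
  a2 <- substr(g, 2, 2)
  out <- paste0(pmin(a1, a2), pmax(a1, a2))
  out[is.na(g)] <- NA_character_
  out
}

validate_genotype_alleles <- function(genotype, snp_row, subject_id) {
  alleles <- strsplit(genotype, "")[[1]]
  allowed <- c(snp_row$effect_allele, snp_row$other_allele)
  bad <- setdiff(alleles, allowed)
  if (length(bad)) {
    stop("subject ", subject_id, ", ", snp_row$rsid, ": genotype ", genotype,
         " contains allele(s) ", paste(bad, collapse = "/"),
         " outside {", paste(allowed, collapse = ","), "}",
         " (no automatic strand flipping; report alleles on the forward strand)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a subject genotype + fitness table
#'
#' Reads a delimited text table with a header naming `id`, one column per panel
#' rsid (two-character genotype strings, order-insensitive), `pre_yoyo_m` and
#' `post_yoyo_m` (Yo-Yo IR1 distances in metres). Extra columns are preserved
#' untouched. Genotype alleles are checked against the panel's effect/other
#' alleles -- a base outside that set is an error, never silently strand-flipped
#' (rs2010963 and rs1042714 are C/G strand-ambiguous, so a flip would be
#' undetectable). Distances that are not multiples of the 40 m Yo-Yo shuttle
#' are flagged with a warning, not rejected.
#'
#' @param source Path to a CSV/TSV file, or a data frame already in memory.
#' @param panel A `tgs_panel`; defaults to [default_panel()].
#' @param sep Field separator when `source` is a path (`","` or `"\t"`;
#'   guessed from the file extension by default).
#' @return A tibble with one row per subject: `id`, one canonicalised genotype
#'   column per panel rsid, `pre_yoyo_m`, `post_yoyo_m`, plus any extra input
#'   columns.
#' @export
read_subject_table <- function(source, panel = default_panel(), sep = NULL) {
  if (is.data.frame(source)) {
    df <- tibble::as_tibble(source)
  } else {
    if (is.null(sep)) {
      sep <- if (tolower(tools::file_ext(source)) %in% c("tsv", "txt")) "\t" else ","
    }
    df <- tibble::as_tibble(utils::read.table(
      source, header = TRUE, sep = sep, colClasses = "character",
      check.names = FALSE, stringsAsFactors = FALSE
    ))
  }
  required <- c("id", panel$rsid, "pre_yoyo_m", "post_yoyo_m")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("subject table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  for (col in c("pre_yoyo_m", "post_yoyo_m")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " for subject(s): ",
           paste(df$id[bad], collapse = ", "), call. = FALSE)
    }
    if (any(x < 0)) {
      stop("negative ", col, " for subject(s): ",
           paste(df$id[x < 0], collapse = ", "), call. = FALSE)
    }
    df[[col]] <- x
  }
  off_grid <- df$pre_yoyo_m %% 40 != 0 | df$post_yoyo_m %% 40 != 0
  if (any(off_grid)) {
    warning("distance not a multiple of the 40 m Yo-Yo shuttle for subject(s): ",
            paste(df$id[off_grid], collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(panel))) {
    rsid <- panel$rsid[i]
    df[[rsid]] <- normalize_genotype(df[[rsid]])
    for (j in seq_len(nrow(df))) {
      validate_genotype_alleles(df[[rsid]][j], panel[i, ], df$id[j])
    }
  }
  df
}

#' Write a subject table as CSV
#'
#' Inverse of [read_subject_table()]: the written file re-reads to an
#' identical tibble (round-trip guaranteed).
#'
#' @param subjects Subject tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract panel genotypes from a VCF
#'
#' Matches VCF records against the panel by the ID field and reconstructs each
#' sample's unordered allele pair from REF/ALT and GT. Alleles are taken as
#' written (reference forward strand); a record whose REF/ALT are not a subset
#' of the SNP's effect/other alleles is rejected rather than strand-flipped.
#' Missing genotypes (`./.`) yield `NA` for that sample/rsid. Records whose ID
#' is not in the panel are ignored.
#'
#' @param source Path to a VCF 4.x file.
#' @param panel A `tgs_panel`.
#' @return A tibble with one row per sample: `id` plus one genotype column per
#'   panel rsid (`NA` where the rsid was absent from the VCF or the GT was
#'   missing).
#' @export
read_vcf_genotypes <- function(source, panel = default_panel()) {
  vcf <- vcfR::read.vcfR(source, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- t(gt)
  samples <- colnames(gt)
  out <- tibble::tibble(id = samples)
  for (rsid in panel$rsid) out[[rsid]] <- NA_character_
  hits <- which(fix$ID %in% panel$rsid)
  for (i in hits) {
    rsid <- fix$ID[i]
    snp_row <- panel[panel$rsid == rsid, ]
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",")[[1]])
    alleles <- c(ref, alts)
    allowed <- c(snp_row$effect_allele, snp_row$other_allele)
    if (!all(alleles %in% allowed)) {
      stop("VCF record ", rsid, ": alleles ", paste(alleles, collapse = "/"),
           " are not a subset of the panel's {",
           paste(allowed, collapse = ","), "}", call. = FALSE)
    }
    for (s in seq_along(samples)) {
      g <- gt[i, s]
      if (is.na(g)) next
      idx <- strsplit(g, "[/|]")[[1]]
      if (any(idx == ".")) next
      pair <- alleles[as.integer(idx) + 1L]
      if (length(pair) != 2L || anyNA(pair)) {
        stop("VCF record ", rsid, ", sample ", samples[s],
             ": cannot decode GT '", g, "'", call. = FALSE)
      }
      out[[rsid]][s] <- paste(sort(pair), collapse = "")
    }
  }
  out
}
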