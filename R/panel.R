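#' Define a single SNP of the trainability panel
#'
#' A panel SNP is identified by its dbSNP rsid and carries the per-genotype
#' point scheme used by the total genotype score: `points` gives the score for
#' 0, 1 and 2 copies of the effect allele. Points live on a 0--4 scale per SNP
#' and must be non-decreasing in effect-allele count.
#'
#' @param rsid dbSNP identifier, e.g. `"rs2010963"`.
#' @param gene Gene symbol, e.g. `"VEGF"`.
#' @param effect_allele Single base (`A`, `C`, `G` or `T`) that earns points.
#' @param other_allele The alternative base; must differ from `effect_allele`.
#' @param points Numeric length-3 vector: points for 0, 1, 2 effect-allele
#'   copies. Defaults to the shipped `c(0, 2, 4)` scheme.
#' @return A one-row tibble with columns `rsid`, `gene`, `effect_allele`,
#'   `other_allele`, `points_0`, `points_1`, `points_2`.
#' @examples
#' snp_definition("rs2010963", "VEGF", "C", "G")
#' @export
snp_definition <- function(rsid, gene, effect_allele, other_allele,
                           points = c(0, 2, 4)) {
  stopifnot(is.character(rsid), length(rsid) == 1L)
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  bases <- c("A", "C", "G", "T")
  if (!effect_allele %in% bases || !other_allele %in% bases) {
    stop("alleles for ", rsid, " must be one of A, C, G, T", call. = FALSE)
  }
  if (effect_allele == other_allele) {
    stop("effect and other allele must differ for ", rsid, call. = FALSE)
  }
  points <- as.numeric(points)
  if (length(points) != 3L || anyNA(points)) {
    stop("`points` must be three numbers (0, 1, 2 effect-allele copies)",
         call. = FALSE)
  }
  if (any(points < 0) || any(points > 4)) {
    stop("genotype points for ", rsid, " must lie in [0, 4]", call. = FALSE)
  }
  if (is.unsorted(points)) {
    stop("genotype points for ", rsid,
         " must be non-decreasing in effect-allele count", call. = FALSE)
  }
  tibble::tibble(
    rsid = rsid, gene = gene,
    effect_allele = effect_allele, other_allele = other_allele,
    points_0 = points[1], points_1 = points[2], points_2 = points[3]
  )
}

#' Build a validated SNP panel
#'
#' @param snps A tibble of SNP definitions, one row per SNP, as produced by
#'   [snp_definition()] (rows are combined with `dplyr::bind_rows()`).
#' @return A `tgs_panel` object: the SNP tibble with a `max_points` attribute
#'   (the largest attainable raw score, the TGS denominator).
#' @seealso [default_panel()], [load_weight_config()]
#' @export
tgs_panel <- function(snps) {
  snps <- dplyr::bind_rows(snps)
  required <- c("rsid", "gene", "effect_allele", "other_allele",
                "points_0", "points_1", "points_2")
  missing <- setdiff(required, names(snps))
  if (length(missing)) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(snps$rsid)) {
    dup <- unique(snps$rsid[duplicated(snps$rsid)])
    stop("duplicate rsid in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(snps) == 0L) stop("panel must contain at least one SNP", call. = FALSE)
  # re-validate each row so hand-built tibbles obey the same invariants
  snps <- purrr::pmap_dfr(snps, function(rsid, gene, effect_allele, other_allele,
                                         points_0, points_1, points_2, ...) {
    snp_definition(rsid, gene, effect_allele, other_allele,
                   points = c(points_0, points_1, points_2))
  })
  max_points <- sum(snps$points_2)
  if (max_points <= 0) stop("panel max_points must be > 0", call. = FALSE)
  structure(snps, class = c("tgs_panel", class(snps)), max_points = max_points)
}

#' Maximum attainable raw score of a panel
#' @param panel A `tgs_panel`.
#' @return A single number, the sum over SNPs of the 2-copy points.
#' @export
panel_max_points <- function(panel) {
  stopifnot(inherits(panel, "tgs_panel"))
  attr(panel, "max_points")
}

#' The shipped five-SNP aerobic-trainability panel
#'
#' The default panel scores VEGF rs2010963, ADRB2 rs1042713 and rs1042714,
#' CRP rs1205 and PPARGC1A rs8192678 at 0/2/4 points for 0/1/2 copies of the
#' effect allele. Effect alleles rs2010963-C and rs8192678-G follow the
#' functional literature on VEGF expression and VO2max; the effect alleles for
#' rs1042713 (G), rs1042714 (G) and rs1205 (C) are configurable assumptions
#' drawn from the association literature, not settled facts -- override them
#' via [load_weight_config()] if your evidence model differs.
#'
#' @return A `tgs_panel` with five SNPs and `max_points = 20`.
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  tgs_panel(list(
    snp_definition("rs2010963", "VEGF",     "C", "G"),
    snp_definition("rs1042713", "ADRB2",    "G", "A"),
    snp_definition("rs1042714", "ADRB2",    "G", "C"),
    snp_definition("rs1205",    "CRP",      "C", "T"),
    snp_definition("rs8192678", "PPARGC1A", "G", "A")
  ))
}

#' Load a panel weight table from a YAML or JSON config
#'
#' The config holds one entry per SNP under a top-level `snps` list (or as the
#' top-level list itself), each with `rsid`, `gene`, `effect_allele`,
#' `other_allele` and optionally `points` (three values for 0/1/2 effect-allele
#' copies; omitted points default to the shipped 0/2/4 scheme). A schema
#' example ships at `system.file("extdata", "default_panel.yaml",
#' package = "aerotrain")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `tgs_panel`.
#' @export
load_weight_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)",
         call. = FALSE)
  )
  entries <- if (!is.null(cfg$snps)) cfg$snps else cfg
  if (!length(entries)) stop("weight config defines no SNPs", call. = FALSE)
  snps <- purrr::map(entries, function(e) {
    if (is.null(e$rsid)) stop("weight config entry lacks an rsid", call. = FALSE)
    pts <- if (is.null(e$points)) c(0, 2, 4) else unlist(e$points)
    snp_definition(
      rsid = e$rsid,
      gene = if (is.null(e$gene)) NA_character_ else e$gene,
      effect_allele = e$effect_allele,
      other_allele = e$other_allele,
      points = pts
    )
  })
  tgs_panel(snps)
}

#' @export
print.tgs_panel <- function(x, ...) {
  cat("<tgs_panel> ", nrow(x), " SNPs, max_points = ",
      panel_max_points(x), "\n", sep = "")
  NextMethod()
  invisible(x)
}
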