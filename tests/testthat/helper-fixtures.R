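# Shared fixtures: all built in code at test time.

# affine-rescale a vector to an exact sample mean and SD
exact_sample <- function(n, mean, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  x <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * x
}

# a hand-written six-subject table covering all three strata
tiny_subject_df <- function() {
  tibble::tibble(
    id = paste0("S", 1:6),
    rs2010963 = c("CC", "CC", "CG", "CG", "GG", "GG"),
    rs1042713 = c("GG", "GG", "AG", "AG", "AA", "AA"),
    rs1042714 = c("GG", "GG", "CG", "CG", "CC", "CC"),
    rs1205    = c("CC", "CC", "CT", "CT", "TT", "TT"),
    rs8192678 = c("GG", "GG", "AG", "AG", "AA", "AA"),
    pre_yoyo_m = c(1000, 1200, 960, 1040, 880, 920),
    post_yoyo_m = c(1560, 1800, 1280, 1400, 920, 1000)
  )
}

# cohort with prescribed per-stratum improvement summaries: each stratum's
# difference scores hit the given mean/SD exactly (pre is arbitrary positive)
cohort_from_diff_summaries <- function(means, sds, ns, seed = 42) {
  set.seed(seed)
  strata <- c("low", "medium", "high")[seq_along(ns)]
  purrr::map_dfr(seq_along(ns), function(g) {
    d <- exact_sample(ns[g], means[g], sds[g])
    pre <- 1000 + stats::rnorm(ns[g], 0, 100)
    tibble::tibble(
      id = sprintf("%s%02d", strata[g], seq_len(ns[g])),
      stratum = strata[g], pre_yoyo_m = pre, post_yoyo_m = pre + d
    )
  })
}

# minimal VCF 4.2 text for the panel SNPs; gt is a named list:
# gt[[rsid]] = c(sample GT strings); ref/alt per rsid supplied alongside
write_test_vcf <- function(path, records, samples) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  for (r in records) {
    lines <- c(lines, paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS",
                              ".", "GT", r$gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
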