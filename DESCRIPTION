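Package: aerotrain
Title: Genotype-Guided Analysis of Aerobic Training Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heterogeneity in aerobic training response as a
    function of a weighted five-SNP total genotype score (TGS). Computes the TGS
    on a 0-100% scale from VEGF rs2010963, ADRB2 rs1042713/rs1042714, CRP rs1205
    and PPARGC1A rs8192678 genotypes, stratifies athletes into low/medium/high
    trainability groups, and provides the complete pre/post field-test analysis:
    group summaries with t-based confidence intervals, paired and pooled-variance
    unpaired t-tests with Bonferroni correction, Cohen's d effect sizes with
    qualitative bands, a 3x2 (Group x Time) split-plot ANOVA with Tukey's HSD,
    responder counts, and both percent-improvement conventions. Includes a
    Hardy-Weinberg synthetic-cohort simulator so the full pipeline is testable
    without subject data, plus summary-statistic entry points that reproduce
    published tables directly from printed means, SDs and group sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
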