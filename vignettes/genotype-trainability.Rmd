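---
title: "Genotype-stratified analysis of aerobic training response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-stratified analysis of aerobic training response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerotrain)
```

## The problem

Two athletes completing the same aerobic training block can see wildly
different fitness gains, and a substantial share of that response variance
is genetic. `aerotrain` operationalises one approach to quantifying it: a
**total genotype score (TGS)** over five SNPs implicated in aerobic
trainability (*VEGF* rs2010963, *ADRB2* rs1042713/rs1042714, *CRP* rs1205,
*PPARGC1A* rs8192678), a stratification of athletes into low / medium / high
expected-response groups, and the full statistical comparison of pre- versus
post-training Yo-Yo Intermittent Recovery distances (metres) between those
strata.

## The score and its assumptions

Each panel SNP awards points for 0, 1 or 2 copies of its effect allele;
points are summed and normalised to the panel maximum, giving a 0–100 %
score; strata cut at ≤ 40 % (low), 40–70 % (medium) and > 70 % (high).

Three design decisions deserve scrutiny:

- **Weights.** Commercial scoring algorithms of this kind keep their
  per-allele weights proprietary. We ship an additive 0/2/4 scheme per SNP —
  the simplest scheme on the documented 0–4 range — and make every weight
  configurable through `load_weight_config()` (YAML/JSON; schema in
  `inst/extdata/default_panel.yaml`). Nothing downstream assumes equal
  weighting.
- **Effect alleles.** rs2010963-C (higher VEGF expression) and rs8192678-G
  (higher VO~2max~ in carriers) follow the functional literature. For
  rs1042713 (G), rs1042714 (G) and rs1205 (C) the trainability-positive
  allele is not settled; our defaults are association-literature choices,
  documented as assumptions and overridable.
- **Strand ambiguity.** rs2010963 and rs1042714 are C/G SNPs, for which a
  strand flip is undetectable from the alleles alone. We therefore never
  strand-flip: genotypes must be reported on the forward strand, and a base
  outside the SNP's allele set is a hard error naming the subject and rsid.

Stratum boundaries are implemented half-open — low is percent ≤ 40, high is
percent > 70, medium is the remainder — which honours all three printed
anchor definitions simultaneously even though weighted percentages need not
be integers. The percent is carried at full floating precision; rounding
happens only in `render_report()`.

Missing genotypes are a hard error by default. An explicit
`permissive = TRUE` mode rescales the denominator to the attainable maximum
of the observed SNPs; scores are then not strictly comparable between
subjects with different missingness patterns, which is why it is off by
default.

## Statistical conventions

All inference runs on one subject-level table (`run_analysis()`), and every
piece is exposed as a standalone function taking either raw vectors or
printed summary statistics, so published tables can be re-derived without
raw data.

- **Confidence intervals** are central-t: `mean ± t((1+γ)/2, n−1) · sd/√n`,
  default γ = 0.90 (the convention of the sport-science literature this
  design follows).
- **t-tests**: paired within strata (one-sample t on differences), Student
  pooled-variance unpaired between strata. Pooled variance, not Welch, is
  the default because the between-group effect sizes use (n−1)-weighted
  pooled SDs — one consistent convention throughout; `ttest = "welch"`
  switches. Zero-variance differences return an infinite statistic with
  `p = 0` and a `degenerate` flag rather than an error.
- **Multiplicity**: the six t-tests (three paired + three unpaired) use a
  Bonferroni-adjusted threshold α/6, printed at 3 decimals (0.008 for
  α = 0.05).
- **Cohen's d**: within-group d divides the pre/post mean change by the
  root-mean-square of the two time-point SDs — the unique simple convention
  consistent with standard pre/post effect-size tables; between-group d uses
  the (n−1)-weighted pooled SD. Bands are contiguous half-open intervals at
  0.2 / 0.5 / 0.8 / 1.2 / 2.0 (trivial → huge): published threshold lists
  are often printed with gaps (e.g. "<0.2" then "0.21–0.5"); contiguous
  intervals assign every finite d exactly one band without changing any
  label at the printed precision.
- **Percent improvement** is reported under *both* conventions — the ratio
  of group means and the mean of per-athlete percentages — because they
  answer different questions and differ substantially in skewed cohorts.
  They are always labelled.

## The split-plot ANOVA

The design is one between-subjects factor (stratum) crossed with a
two-level within-subjects factor (time). With exactly two time points the
within-subject tests are exact functions of per-subject difference scores
`d = post − pre`: the Group × Time interaction is a one-way ANOVA on `d`,
and the time main effect tests the grand mean of `d`. The group effect is
tested against the between-subjects error (subject means), time and
interaction against the within-subjects error; degrees of freedom total
2N − 1, and sphericity is not an issue at two levels.

Strata are unbalanced, so the effect sums of squares need a weighting
convention. The default is **Type III** (unweighted group means with a
harmonic-mean effective group size) — the convention of mainstream
commercial ANOVA software, and the one under which printed F statistics of
unbalanced pre/post designs are recoverable from per-group summary
statistics via `anova_from_summaries()`. A sums-over-observations
`type = "weighted"` variant is available; the two coincide on balanced
designs (verified in the test suite against both an `aov()` oracle and a
brute-force cell-means decomposition).

Effects with zero sum of squares report `F = 0` even when the error mean
square is also zero (an all-identical-responses cohort), so degenerate
inputs produce a well-defined table.

**Tukey's HSD** uses the Tukey–Kramer statistic
`q = |Δmean| / √(MSE/2 · (1/nᵢ + 1/nⱼ))` with adjusted p-values from the
studentized-range distribution (`stats::ptukey`, a numerical-integration
implementation; the suite cross-checks it against a 10⁶-draw Monte-Carlo
simulation of the range of normal means over a chi-distributed scale). In
`run_analysis()` the follow-up runs on subject means (the average of each
athlete's two time points), matching its role as the follow-up to the
between-subjects effect.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a genotyped squad:

- **Genotypes** are drawn per SNP under Hardy–Weinberg equilibrium
  (p², 2pq, q²), independently across SNPs and subjects. The default effect
  allele frequency of 0.5 at every SNP puts ≈ 57 % of subjects in the
  medium stratum under the 0/2/4 weights, matching the design expectation
  that roughly 60 % of athletes score 40–70 %.
- **Baseline**: pre-training distance ~ Normal(1015 m, 450 m), truncated to
  positive values by resampling (so per-athlete percent improvements stay
  defined).
- **Response**: `improvement = −335 + 11.5 · TGS% + Normal(0, 225 m)`;
  post = pre + improvement, floored at 0 m. The intercept/slope/noise
  defaults are invented back-of-envelope fits to published stratum-level
  improvement summaries on this scale — they give ≈ 125 m mean improvement
  at TGS 40 % and ≈ 470 m at 70 % — and are not measured constants.
  Negative improvements are permitted (real squads contain decrementers);
  only physically impossible negative distances are clipped.
- **Quantisation**: Yo-Yo distances come in 40 m shuttles;
  `round_to_shuttle = TRUE` snaps to that grid. It is off by default so
  that distributional checks see continuous data, and the table reader
  emits a lint warning (not an error) for off-grid distances.

One integer seed reproduces the whole cohort bitwise. The generator is
deliberately simple: no linkage disequilibrium between SNPs, no
age/maturation covariates, a single Gaussian noise term rather than a
test-retest measurement-error model, and a linear (not saturating)
TGS–response link. Passing tests on simulated cohorts therefore demonstrate
the *statistical machinery* — not that real training responses are linear in
a genotype score.

`recover_response_slope()` closes the loop: OLS of improvement on TGS
percent recovers the generating slope, and the suite checks 2-SE coverage
over 200 seeded replicates of n = 2000 cohorts (sizes chosen to keep the
whole suite in the tens of seconds while leaving the Monte-Carlo error well
inside the asserted bounds; the distributional checks use n = 20 000
genotype draws and 2000 CI replicates for the same reason).

## Degenerate inputs and graceful degradation

Strata with fewer than two subjects are summarised but excluded from
inference; with fewer than two testable strata the ANOVA/Tukey block is
marked not-computable and everything else still renders. Ties and empty
blocks never crash report rendering, and regenerating a report from the same
inputs is byte-identical. Statistical code never rounds; the formatting
layer rounds distances to whole metres, d to 2 decimals and percentages to
1 decimal.

## Known limitations

- The exact commercial weights, and the effect alleles for three of the
  five SNPs, are assumptions; conclusions about a specific commercial score
  require its true weight table via `load_weight_config()`.
- The between-subjects (group) F from `anova_from_summaries()` is not
  available — it requires pre/post correlations that per-period summary
  tables do not carry; the function flags its output `partial`.
- A published low-stratum pre-training 90 % CI upper bound can differ by
  1 m from the value this package computes from the rounded printed
  mean/SD; interval reproduction from printed summaries is exact only up to
  input rounding.
- No imputation, liftover, dbSNP lookup or multi-sample phasing; VCF input
  is matched purely on the ID column.
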