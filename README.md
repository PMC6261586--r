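# aerotrain

Aerobic training response varies enormously between athletes doing identical
training, and part of that variability is heritable. `aerotrain` implements a
genotype-guided analysis of that heterogeneity for sport and exercise
scientists: it scores athletes on a weighted five-SNP **total genotype score
(TGS)**, stratifies them into low / medium / high aerobic-trainability
groups, and runs the complete pre/post field-test comparison between the
strata — the workflow used to ask whether a genetic panel predicts who will
respond to an aerobic training block, as measured by the Yo-Yo Intermittent
Recovery test (distance in metres).

## The model

**Score.** Each SNP of the panel (*VEGF* rs2010963, *ADRB2* rs1042713 and
rs1042714, *CRP* rs1205, *PPARGC1A* rs8192678) awards points for 0/1/2
copies of its effect allele (default 0/2/4, each weight configurable within
the 0–4 range). The TGS is the summed points as a percentage of the panel
maximum:

```
TGS% = 100 · Σᵢ points_i(genotype_i) / Σᵢ max points_i
```

Strata partition the percent scale: ≤ 40 % "low", (40, 70] "medium",
\> 70 % "high".

**Inference.** For pre/post distances `y` and improvements `d = post − pre`:

- group summaries as mean ± SD with central-t 90 % CIs,
  `x̄ ± t₀.₉₅,ₙ₋₁ · s/√n`;
- paired t-tests within strata, Student pooled-variance unpaired t-tests
  between strata, at a Bonferroni-adjusted threshold `α/k` for the `k = 6`
  tests;
- Cohen's d with qualitative bands (0.2/0.5/0.8/1.2/2.0): within-group
  `d = Δx̄ / √((s²_pre + s²_post)/2)`, between-group `d = |Δx̄| / s_pooled`;
- a 3×2 (Group × Time) split-plot ANOVA with repeated measures on time,
  Type III (unweighted-means) sums of squares for the unbalanced strata, and
  Tukey–Kramer HSD follow-up;
- responder counts above 120 m / 500 m improvement cut-offs, and both
  percent-improvement conventions (ratio of group means, and mean of each
  athlete's own percentage — they differ, and published reports mix them).

A Hardy–Weinberg synthetic-cohort generator (`simulate_cohort()`) emulates a
~42-player squad with a TGS-linked linear response model, so the entire
pipeline is testable without subject data, and summary-statistic entry
points (`ci_mean_t()`, `cohen_d_prepost()`, `cohen_d_independent()`,
`anova_from_summaries()`) reproduce published tables directly from printed
means, SDs and group sizes.

## Worked example

```r
library(aerotrain)

cohort <- simulate_cohort(simulation_config(n_subjects = 42, seed = 7,
                                            round_to_shuttle = TRUE))
report <- run_analysis(cohort)
report
```

```
Genotype-stratified training-response report
n = 42 subjects in 3 strata (low=14, medium=24, high=4)
conventions: pooled unpaired t, type III ANOVA, 90% CI, alpha 0.05 (6 t-tests, Bonferroni-adjusted 0.008)
...
Improvement by stratum [mean (SD; CI)]; percent by both conventions
  low     160 (268; 33 to 287)   ratio-of-means 13.1%   mean-individual 12.1%
  medium  357 (267; 263 to 450)   ratio-of-means 32.8%   mean-individual 39.4%
  high    620 (208; 375 to 865)   ratio-of-means 65.3%   mean-individual 94.9%
...
Split-plot ANOVA (type III)
  group                        F(2, 39) = 0.0, p 0.9814
  time                         F(1, 39) = 51.5, p <0.0001
  group:time                   F(2, 39) = 6.4, p 0.0040
```

Read it as: the three genotype strata start equivalently fit (trivial group
effect), everyone improves over the training block (large time effect), and —
the question of interest — the *size* of the improvement climbs with the
genotype score (significant Group × Time interaction; mean improvement
160 m → 357 m → 620 m from low to high). `tidy(report)` returns the summary
tibble, `glance(report)` the one-row model overview, and
`plot_individual_improvements(report)` the per-athlete response chart that
makes the heterogeneity visible. Real data enter through
`read_subject_table()` (CSV/TSV) or `read_vcf_genotypes()` (VCF 4.x matched
by rsID), and `render_report(report, "tsv" | "json")` exports every block.

A command-line wrapper with `score` / `analyze` / `simulate` / `reproduce`
subcommands ships at `inst/scripts/tgs-pipeline.R`.

## Caveats

The exact per-SNP weights of the commercial algorithm that motivated this
design are unpublished; the shipped 0/2/4 scheme preserves its 0–4 range and
additive structure and every weight is overridable via
`load_weight_config()`. The effect-allele choices for rs1042713, rs1042714
and rs1205 are literature-based configurable assumptions. The TGS stratifies
*trainability*, not talent: absolute test scores are not predicted by it.
See the methods vignette (`vignettes/genotype-trainability.Rmd`) for the
full statistical conventions and the simulator's design.
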