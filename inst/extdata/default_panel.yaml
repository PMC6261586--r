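# Shipped five-SNP aerobic-trainability weight table.
# points = score for 0 / 1 / 2 copies of the effect allele (each in [0, 4]).
# Effect alleles for rs1042713, rs1042714 and rs1205 are configurable
# literature-based assumptions; override here if your evidence model differs.
snps:
  - rsid: rs2010963
    gene: VEGF
    effect_allele: C
    other_allele: G
    points: [0, 2, 4]
  - rsid: rs1042713
    gene: ADRB2
    effect_allele: G
    other_allele: A
    points: [0, 2, 4]
  - rsid: rs1042714
    gene: ADRB2
    effect_allele: G
    other_allele: C
    points: [0, 2, 4]
  - rsid: rs1205
    gene: CRP
    effect_allele: C
    other_allele: T
    points: [0, 2, 4]
  - rsid: rs8192678
    gene: PPARGC1A
    effect_allele: G
    other_allele: A
    points: [0, 2, 4]
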