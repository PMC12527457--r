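# tierpoi

Tiered exome-sequencing variant prioritization for cohorts of women with
early-onset primary ovarian insufficiency (POI).

## What it does, and for whom

POI — loss of ovarian function before 40 with raised FSH — has a
heterogeneous genetic basis: variants in >100 genes, under recessive,
dominant and oligogenic/polygenic models, with very uneven evidence per
gene. For an analyst screening an exome-sequenced POI cohort, `tierpoi`
turns that mess into a deterministic, auditable pipeline:

1. **Filtering cascade** per annotated call, five stages evaluated in
   order and all reported: call quality ≥ 20 and depth ≥ 10; ≥ 2 of 3
   in-silico damaging verdicts (CADD > 15, PolyPhen2, SIFT); gnomAD
   allele frequency < 0.01% for biallelic context or < 0.005% for single
   heterozygous/polygenic variants (strict; novel passes); synonymous
   changes excluded unless splice-relevant (±7 bases into an intron, or
   a splice-loss prediction); ACMG Pathogenic/Likely Pathogenic only. An
   established-POI allowlist flag bypasses every stage except quality.
2. **Three-tier category routing** per gene finding: Category 1 = expert
   panel gene (green/amber/red tier) with expected inheritance; Category
   2 = literature-curated gene, or a panel gene with *unexpected*
   inheritance (e.g. a lone het in a recessive gene, rerouted); Category
   3 = homozygous variant in an unlisted gene — the forward screen for
   novel candidates, run cohort-wide.
3. **Zygosity and inheritance labels**: homozygous / probable compound
   het (phase never assumed) / heterozygous per gene; one label per
   individual — oligogenic (≥ 2 genes, at least one het), else AR, CH,
   AD. Category 3 never contributes.
4. **Kindred aggregation** for familial cases: per-gene intersection of
   variant sets across recruited affected members, with segregation
   checks against genotyped unaffected relatives.
5. **Cohort summaries**: detection rates per category and mode at
   sporadic (individual), familial (kindred) and merged entity level,
   plus familial-vs-sporadic Fisher contrasts.

Statistics: the two-tailed Fisher exact test is a full hypergeometric
enumeration with the point-probability two-sided rule (p = Σ P(table)
over tables with the observed margins whose point probability ≤ that of
the observed table); multiple testing uses Benjamini–Hochberg, with
cohort-vs-gnomAD enrichment significant at adjusted p < 1e-4.

The package also ships a deterministic **synthetic-cohort generator**
(`generate_cohort()`) with a truth manifest and stage-targeted decoys,
and plain-text **fixtures encoding the published familial and sporadic
variant tables** so every printed detection-rate statistic is
recomputable offline.

## Worked example

```r
library(tierpoi)

fx  <- make_table_fixtures()   # published-table cohorts + panels
scr <- poi_screen(fx$combined$calls, fx$combined$annotations,
                  fx$combined$pedigree, fx$panel1, fx$panel2,
                  other_phenotype_genes = fx$other_phenotype_genes$gene)
summary(scr)
```

```
Cohort summary (tiered POI screen)
  cohort: 118 sporadic individuals; 17 familial kindreds (31 women)
  sporadic: 75/118 (63.6%) with Category 1/2 finding; cat1 25 (21.2%), cat2-only 50 (42.4%)
  familial: 11/17 (64.7%) kindreds with Category 1/2 finding; cat1 6 (35.3%), cat2-only 5 (29.4%)
  merged entities with findings: 86; modes: AD 46 (53.5%), AR 10 (11.6%), CH 2 (2.3%), oligogenic 28 (32.6%)
  Category 1/2: 76 distinct genes, 127 distinct variants
  Category 3 candidate carriers: 7 women
  homozygous (AR) label, familial kindreds vs sporadic individuals: [[5,12],[5,113]] p = 0.003004 (significant)
  single heterozygous (AD) label, familial kindreds vs sporadic individuals: [[3,14],[43,75]] p = 0.1733
```

Reading this: 63.6% of sporadic individuals carry at least one Category
1/2 finding (21.2% a Category 1 finding, a further 42.4% Category 2
only); 11 of 17 familial kindreds (64.7%) have a shared kindred-level
finding; treating each sporadic woman and each familial kindred as one
entity, 86 entities carry findings, labeled AD 46, AR 10, CH 2,
oligogenic 28; seven women carry candidate (Category 3) homozygotes in
genes not previously POI-associated; and homozygous findings are
significantly more frequent in familial than sporadic POI.

Per-finding detail is in `scr$findings` (sample, gene, zygosity,
category, tier, reroute reason), kindred-level results in
`scr$kindred_findings`, per-variant enrichment in `scr$enrichment`, and
per-stage rejection counts in `scr$log`. `run_screen()` /
`run_summarize()` / `run_simulate()` are the file-based equivalents.

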