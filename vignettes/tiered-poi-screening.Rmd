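---
title: "Tiered exome variant prioritization for early-onset POI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered exome variant prioritization for early-onset POI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierpoi)
```

## The problem

Primary ovarian insufficiency (POI) — loss of ovarian function before age
40 with raised FSH — has a strikingly heterogeneous genetic architecture:
over a hundred genes have been associated with it, under autosomal
recessive, autosomal dominant and oligogenic/polygenic models, and the
strength of evidence behind individual gene–disease links varies widely.
When a cohort of affected women is exome-sequenced, the analyst must
decide, variant by variant, what counts as a plausible finding without
presenting poorly supported variants as diagnoses. `tierpoi` implements a
tiered, rule-based prioritization for this setting: a deterministic
filtering cascade, explicit evidence tiers for gene categories, zygosity
and inheritance-mode labeling, kindred-level aggregation for familial
cases, and cohort summaries — all reproducible from a VCF (or annotated
variant table), a pedigree and two gene-panel files.

The package deliberately starts *after* alignment, variant calling and
functional annotation: those are consumed as inputs (an annotated variant
table with gene, consequence, gnomAD v4-style frequency and allele
counts, CADD/PolyPhen2/SIFT verdicts, an ACMG class, and optionally a
splice-loss prediction). No annotation is computed in-package.

## The filtering cascade

Each per-sample call carrying an alternate allele passes through five
stages, all evaluated so a rejected call reports every stage it failed:

1. **Quality** — call quality ≥ 20 and read depth ≥ 10, both inclusive.
   This stage is unconditional.
2. **In-silico deleteriousness** — at least 2 of 3 damaging verdicts:
   CADD strictly above 15, PolyPhen2 damaging, SIFT deleterious. A
   missing verdict is a non-vote (conservative: missing data can only
   shrink the retained set).
3. **Rarity** — gnomAD allele frequency strictly below 0.01% (1e-4) for
   variants in a *biallelic* context (homozygous, or member of a probable
   compound-het pair) and strictly below 0.005% (5e-5) for single
   heterozygous/polygenic variants. Absent-from-gnomAD counts as novel
   and passes.
4. **Synonymous/splice** — synonymous changes are excluded unless
   predicted to affect splicing; intronic and splice-site changes are
   retained when they lie within 7 bases of the exon boundary *or* carry
   a splice-loss prediction. The two retention routes are alternatives:
   a canonical ±7 splice-site loss needs no external prediction, and a
   deep-intronic change can be rescued by one.
5. **ACMG class** — only Pathogenic / Likely Pathogenic calls are
   retained; a missing class fails.

A per-variant *established-POI allowlist flag* bypasses stages 2–5 (never
stage 1). This models the curator's override for variants with a
well-established relationship to POI pathogenesis: such variants are
retained even where, for example, their population frequency exceeds the
rarity threshold — the published tables this package reproduces contain
several such variants (the classic BMP15 p.L148P at gnomAD frequency
0.0076 being the clearest), so the override must cover the whole
retention list, not just the in-silico vote.

The rarity stage depends on the gene's zygosity class, which itself can
change when a variant is removed (a two-het pair losing one member
becomes a lone het and faces the stricter threshold), so the pipeline
iterates zygosity resolution and rarity filtering to a fixed point. The
iteration only removes calls, so it terminates.

## Zygosity, categories and inheritance labels

Per sample and gene, surviving calls resolve to one of three classes: any
homozygous-alt call makes the gene **homozygous**; two or more distinct
heterozygous variants make it a **probable compound het** (phase is never
assumed — if both genotyped parents prove the pair cis, it collapses to
its rarer member); a single het is **heterozygous**.

Category routing is a total decision order: (1) gene on the expert panel
(panel 1) with zygosity compatible with its expected inheritance →
Category 1 with the panel tier (green/amber/red); (2) panel-1 gene with
incompatible zygosity (e.g. a lone het in a recessive gene) → Category 2,
flagged `unexpected_inheritance`; (3) gene on the literature-curated
panel 2 → Category 2; (4) homozygous in an unlisted gene → Category 3,
the forward screen for novel candidates; (5) anything else is discarded.
Probable compound het counts as biallelic for the expected-inheritance
match. The Category 3 pass runs cohort-wide, so women with Category 1/2
findings still surface candidate homozygotes. A configurable
other-phenotype gene list flags homozygous findings that likely explain a
different clinical feature (e.g. situs inversus, rod–cone dystrophy);
flagged findings stay in the reports but leave the candidate counts.

Each individual with at least one Category 1/2 finding receives exactly
one inheritance label. Findings in two or more distinct genes, at least
one of them a single heterozygous finding, label the individual
**oligogenic**; otherwise any homozygous finding labels **AR**, a
compound het labels **CH**, a lone het labels **AD**. Category 3 findings
never enter the count. The at-least-one-heterozygous condition is
deliberate: an individual homozygous in two genes is reported as AR (two
independent recessive findings), while every mixed multi-gene case is
oligogenic/polygenic — this is the labeling evidenced row-by-row in the
tables the fixtures encode.

For familial kindreds, findings aggregate per gene by intersecting the
variant sets of all recruited affected members; a gene absent from any
member is not a kindred finding. Unaffected relatives, where genotyped,
drive a segregation status (an unaffected homozygote breaks an AR
finding; an unaffected carrier breaks an AD finding under an assumed full
penetrance); inconsistent findings are flagged, never dropped, and
kindreds without genotyped relatives are `untestable`.

## Statistics

Cohort-vs-gnomAD enrichment uses the two-tailed Fisher exact test on
allele counts, `[[cohort_ac, cohort_an − cohort_ac], [pop_ac, pop_an −
pop_ac]]`. The test is a full hypergeometric enumeration with the
point-probability ("minimum-likelihood") two-sided rule and a 1e-7
relative tie tolerance — the convention of mainstream statistical
software; the test suite checks it exhaustively against an independent
log-binomial enumeration for every 2×2 table with total n ≤ 60 and
against `stats::fisher.test` on sampled tables. Multiple testing uses
Benjamini–Hochberg (delegated to `stats::p.adjust`); the adjustment
family is all variants surviving the quality and in-silico stages in the
run, recorded in the run log. Enrichment significance (adjusted p <
1e-4 by default) is reported alongside findings but is not a retention
gate: with gnomAD-scale denominators, a cohort singleton cannot reach
that bound, so gating would empty every table. Subcohort contrasts
(familial kindreds vs sporadic individuals, per inheritance mode) use the
same Fisher test at α = 0.05, entity-level, with whole-subcohort
denominators.

Percentages are computed on exact counts and rounded half-up to one
decimal only for presentation.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 118 sporadic probands
plus 17 familial kindreds with two recruited affected sisters each, 8/17
kindreds consanguineous. Per entity it samples a plant type — Category 1
AR/AD/CH, Category 2 AD/CH, oligogenic (one panel-1 plus one panel-2
het), candidate homozygote, other-phenotype homozygote, or no finding —
with default probabilities equal to the fixture cohort's observed
composition (e.g. 5/118 sporadic AR, 26/118 oligogenic, 6/17 kindreds
finding-free). Consanguineous kindreds draw from a composition with the
AR weight tripled and renormalized, reflecting the recessive enrichment
consanguinity produces. Planted variants satisfy every filter by
construction (quality 30–99, depth 20–150, CADD 16–45 with both other
votes damaging, P/LP class, frequencies drawn uniformly below half the
context threshold on a 1.6-million-allele gnomAD-scale denominator).
Decoys — by default one per cascade stage per individual — violate
exactly their stage while passing all others, so the pipeline must reject
each at the constructed stage; `ablate()` perturbs every *planted*
variant to violate one named stage for the complementary test. Everything
is deterministic given the seed; writing and re-reading a bundle is
hash-stable.

What the generator does *not* emulate: linkage disequilibrium, haplotype
structure, read-level errors, annotation disagreement between
transcripts, population stratification of allele frequencies, or variants
that sit near the filter boundaries. Passing the recovery tests therefore
demonstrates the pipeline's bookkeeping is exact under clean inputs, not
that the thresholds are clinically optimal on real exomes.

## The published-table fixtures

The familial and sporadic variant tables of the study the pipeline
models are shipped as plain-text fixtures (with synthetic coordinates;
gene symbols, transcripts, HGVS strings, zygosities and literal printed
gnomAD frequencies preserved), together with panel files encoding each
panel gene's tier and expected inheritance as evidenced by the tables'
own placements (a gene whose lone hets are printed under "Category 2" is
biallelic-expected; one whose hets are printed as Category 1 is
monoallelic-expected). Running the full pipeline on these fixtures
reproduces every printed row's category and every printed detection-rate
statistic; `scripts/acceptance.R` recomputes them from scratch.

Three reporting quirks of the source tables are worth knowing. First,
the printed familial homozygosity proportion (35.3%, 6/17) does not match
the familial table, which contains five AR kindreds (29.4%) — the
package reports the table-derived value. Second, the merged
inheritance-mode percentages are printed against a denominator of 86
entities but equal n/87; the package reports exact shares of its actual
86 entities with findings (AD 53.5%, AR 11.6%). Third, one kindred
carries homozygous variants in two genes yet is labeled AR, which is why
the oligogenic rule requires a heterozygous member. These are documented,
not "fixed": the fixtures encode the tables as printed.

## Numerical and design choices

- Thresholds are strict exactly where the source criteria read as strict
  (CADD > 15, MAF < 1e-4 / 5e-5) and inclusive where they read inclusive
  (quality ≥ 20, depth ≥ 10); boundary behavior is pinned by tests.
- Multi-allelic VCF records decompose into one call per sample per alt
  allele; genotypes of ploidy other than 2 degrade to missing with a
  warning (the intended cohort is 46,XX, so no hemizygous rule exists).
  X-linked hets are treated exactly like autosomal hets.
- Positions are 1-based throughout, as in VCF.
- The Fisher tie tolerance (1e-7, relative) absorbs floating-point
  near-ties among hypergeometric point probabilities; without it,
  mathematically tied tables can fall on either side of the observed
  probability depending on rounding.
- Kindred aggregation requires sharing across *recruited affected*
  members only; a single-member familial kindred passes through with
  segregation `untestable`.
- An empty cohort errors; an empty findings set yields a zero-filled
  summary with explicit zero rows in the reports.

## Problem sizes used in the checks

The shipped verification suite runs the full fixtures (149 affected
individuals, 141 printed variant rows), an exhaustive Fisher comparison
over all 635,375 tables with total n ≤ 60, and synthetic-recovery runs at
the default cohort size (135 affected individuals, ~790 variants
including decoys) plus smaller seeds-and-sizes variants; the whole suite
completes in well under a minute of compute per component.

## Limitations

The pipeline's tiers are only as good as the panels supplied; the
shipped panels are reconstructions from the published tables' placements,
not the full expert panel (whose supplementary listing is not public
data). ACMG classes and in-silico verdicts are consumed, not audited.
Phase is never statistically inferred: compound hets remain "probable"
without parental genotypes. Segregation checking assumes full penetrance
for AD findings, which flags — by design — carrier parents of late-onset
phenotypes. Enrichment against gnomAD treats the population as a control
cohort without ancestry matching.
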