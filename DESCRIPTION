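Package: tierpoi
Title: Tiered Exome Variant Prioritization for Early-Onset Primary Ovarian Insufficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tiered exome-sequencing variant prioritization pipeline for
    cohorts of women with early-onset primary ovarian insufficiency (POI).
    Implements a five-stage filtering cascade (call quality, 2-of-3 in-silico
    deleteriousness with a CADD cutoff, gnomAD rarity with zygosity-dependent
    thresholds, synonymous/splice retention, ACMG class), cohort-versus-gnomAD
    Fisher exact enrichment with Benjamini-Hochberg adjustment, three-tier
    gene-category routing with unexpected-inheritance rerouting and a
    homozygous forward screen for novel candidate genes, per-individual
    zygosity and inheritance-mode labeling, kindred-level aggregation with
    segregation checks, and cohort summarization. Ships a deterministic
    synthetic-cohort generator with a truth manifest, and plain-text fixtures
    encoding the published familial and sporadic variant tables so every
    printed detection-rate statistic is recomputable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
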