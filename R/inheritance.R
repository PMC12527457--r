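#' Resolve the zygosity class of one sample's calls in one gene
#'
#' Classification: any homozygous-alt call makes the gene `homozygous`;
#' otherwise two or more distinct heterozygous variants make it
#' `probable_compound_het` (phase is never assumed -- without parental
#' genotypes two hets are only *probable* trans); a single het is
#' `heterozygous`.
#'
#' @param genotypes Vector of `"het"`/`"hom_alt"` genotype tokens.
#' @param keys Variant keys, same length.
#' @return One of `"homozygous"`, `"probable_compound_het"`,
#'   `"heterozygous"`.
#' @export
resolve_gene_zygosity <- function(genotypes, keys) {
  if (!length(genotypes)) stop("zygosity resolution requires at least one call")
  stopifnot(length(genotypes) == length(keys),
            all(genotypes %in% c("het", "hom_alt")))
  if (any(genotypes == "hom_alt")) return("homozygous")
  if (length(unique(keys)) >= 2L) return("probable_compound_het")
  "heterozygous"
}

#' Rarity context implied by a gene's zygosity class
#'
#' Homozygous and probable-compound-het members take the biallelic
#' frequency threshold; a lone heterozygous variant takes the stricter
#' monoallelic one.
#'
#' @param zyg_class Zygosity class from [resolve_gene_zygosity()].
#' @return `"biallelic"` or `"monoallelic"` (vectorized).
#' @export
rarity_context <- function(zyg_class) {
  stopifnot(all(zyg_class %in% c("homozygous", "probable_compound_het", "heterozygous")))
  ifelse(zyg_class == "heterozygous", "monoallelic", "biallelic")
}

#' Inheritance-mode label for one individual (or kindred)
#'
#' Only Category 1/2 findings count; Category 3 findings never contribute.
#' Precedence: findings in two or more distinct genes of which at least one
#' is a single heterozygous finding are labeled `oligogenic`; otherwise any
#' homozygous finding labels `AR`, any probable compound het labels `CH`,
#' and a remaining single heterozygous finding labels `AD`. (The
#' at-least-one-heterozygous condition keeps an individual with two
#' independently homozygous genes labeled `AR`, matching how such cases are
#' reported; every multi-gene case with a heterozygous member is
#' oligogenic/polygenic regardless of any other member's zygosity.)
#'
#' @param genes Gene symbol per finding.
#' @param zyg_class Zygosity class per finding.
#' @param category Category (1, 2 or 3) per finding.
#' @return `"oligogenic"`, `"AR"`, `"CH"`, `"AD"`, or `NA_character_` when
#'   there is no Category 1/2 finding.
#' @export
label_inheritance <- function(genes, zyg_class, category) {
  keep <- category %in% c(1L, 2L)
  genes <- genes[keep]; zyg_class <- zyg_class[keep]
  if (!length(genes)) return(NA_character_)
  if (length(unique(genes)) >= 2L && any(zyg_class == "heterozygous")) {
    return("oligogenic")
  }
  if (any(zyg_class == "homozygous")) return("AR")
  if (any(zyg_class == "probable_compound_het")) return("CH")
  "AD"
}
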