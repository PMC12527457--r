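#' Route one gene-level finding to Category 1, 2 or 3
#'
#' Decision order, a total function of panel membership, expected
#' inheritance and zygosity:
#' 1. gene on panel 1 with zygosity compatible with its expected
#'    inheritance -> Category 1 with the panel tier;
#' 2. gene on panel 1 with incompatible zygosity -> Category 2 with
#'    `reroute_reason = "unexpected_inheritance"` (e.g. a single
#'    heterozygous variant in a recessive panel gene);
#' 3. gene on panel 2 -> Category 2;
#' 4. homozygous in an unlisted gene -> Category 3 (candidate-gene forward
#'    screen);
#' 5. otherwise (heterozygous or compound het in an unlisted gene) ->
#'    discard.
#' Probable compound het counts as biallelic for expected-inheritance
#' matching.
#'
#' @param gene Gene symbol.
#' @param zyg_class Zygosity class from [resolve_gene_zygosity()].
#' @param panel1,panel2 Panels from [read_gene_panel()] (checked disjoint).
#' @return List with `category` (1/2/3 or NA for discard), `tier`,
#'   `reroute_reason`.
#' @export
classify_finding <- function(gene, zyg_class, panel1, panel2) {
  zyg_mode <- if (zyg_class == "heterozygous") "monoallelic" else "biallelic"
  i1 <- match(gene, panel1$gene)
  if (!is.na(i1)) {
    expected <- strsplit(panel1$expected_inheritance[i1], "[|,]")[[1L]]
    if (zyg_mode %in% expected) {
      return(list(category = 1L, tier = panel1$tier[i1], reroute_reason = "none"))
    }
    return(list(category = 2L, tier = "none", reroute_reason = "unexpected_inheritance"))
  }
  if (gene %in% panel2$gene) {
    return(list(category = 2L, tier = "none", reroute_reason = "none"))
  }
  if (zyg_class == "homozygous") {
    return(list(category = 3L, tier = "none", reroute_reason = "none"))
  }
  list(category = NA_integer_, tier = "none", reroute_reason = "none")
}

#' Flag findings in genes explaining a non-ovarian phenotype
#'
#' Some homozygous findings (e.g. in genes definitively associated with
#' situs inversus or rod-cone dystrophy) likely explain other aspects of a
#' participant's presentation rather than the ovarian phenotype. Flagged
#' findings are excluded from POI-candidate counts but retained in all
#' reports.
#'
#' @param findings Findings data.frame with a `gene` column.
#' @param other_phenotype_genes Character vector (or data.frame with a
#'   `gene` column) of genes to flag.
#' @return `findings` with a logical `other_phenotype_flag` column set.
#' @export
flag_other_phenotype <- function(findings, other_phenotype_genes = character()) {
  if (is.data.frame(other_phenotype_genes)) {
    other_phenotype_genes <- other_phenotype_genes$gene
  }
  findings$other_phenotype_flag <- findings$gene %in% other_phenotype_genes
  findings
}
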