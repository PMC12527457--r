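#' Aggregate per-individual findings to kindred level
#'
#' For every kindred, per gene, the kindred-level finding is the
#' intersection of the affected recruited members' variant sets; a gene is
#' only reported when every affected recruited member shares at least one
#' variant in it. The shared zygosity class is re-derived from the member
#' calls restricted to the shared variants; members discordant in zygosity
#' mark the finding `inconsistent` (retained and flagged, never silently
#' dropped). Category routing is re-applied to the shared zygosity.
#' Singleton kindreds (sporadic individuals, or familial kindreds with one
#' recruited affected member) pass through with segregation `untestable`
#' unless unaffected relatives were genotyped.
#'
#' @param findings Per-individual findings (from [poi_screen()]).
#' @param calls Annotated calls for the whole pedigree (used for unaffected
#'   relatives' genotypes in segregation checks).
#' @param pedigree Pedigree data.frame.
#' @param panel1,panel2 Gene panels.
#' @param other_phenotype_genes Other-phenotype gene list.
#' @return List with `findings` (kindred-level data.frame incl.
#'   `segregation_status`) and `labels` (one inheritance label per kindred
#'   with findings).
#' @export
aggregate_kindred <- function(findings, calls, pedigree, panel1, panel2,
                              other_phenotype_genes = character()) {
  empty <- data.frame(kindred_id = character(), gene = character(),
                      shared_variant_keys = character(), zygosity = character(),
                      category = integer(), tier = character(),
                      n_affected_members = integer(),
                      segregation_status = character(),
                      other_phenotype_flag = logical(), stringsAsFactors = FALSE)
  kin_ids <- unique(pedigree$kindred_id[pedigree$affected])
  rows <- list()
  for (kid in kin_ids) {
    members <- pedigree$sample_id[pedigree$kindred_id == kid & pedigree$affected]
    unaffected <- pedigree$sample_id[pedigree$kindred_id == kid & !pedigree$affected]
    unaffected_gt <- calls[calls$sample_id %in% unaffected, , drop = FALSE]
    fk <- findings[findings$sample_id %in% members, , drop = FALSE]
    if (!nrow(fk)) next
    for (gene in sort(unique(fk$gene))) {
      fg <- fk[fk$gene == gene, , drop = FALSE]
      if (length(unique(fg$sample_id)) < length(members)) next
      keysets <- lapply(split(fg$variant_keys, fg$sample_id),
                        function(v) unlist(strsplit(v, ",", fixed = TRUE)))
      shared <- Reduce(intersect, keysets)
      if (!length(shared)) next
      member_zyg <- .shared_zygosity(fg, shared)
      discordant <- length(unique(member_zyg)) > 1L
      zyg <- member_zyg[1L]
      cl <- classify_finding(gene, zyg, panel1, panel2)
      if (is.na(cl$category)) next
      status <- if (discordant) "inconsistent" else {
        check_segregation(zyg, shared, unaffected_gt)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kindred_id = kid, gene = gene,
        shared_variant_keys = paste(sort(shared), collapse = ","),
        zygosity = zyg, category = cl$category, tier = cl$tier,
        n_affected_members = length(members),
        segregation_status = status,
        other_phenotype_flag = gene %in% other_phenotype_genes,
        stringsAsFactors = FALSE)
    }
  }
  kf <- if (length(rows)) do.call(rbind, rows) else empty
  kf <- kf[order(kf$kindred_id, kf$gene), , drop = FALSE]
  rownames(kf) <- NULL
  use <- kf[!kf$other_phenotype_flag, , drop = FALSE]
  kids <- unique(use$kindred_id[use$category %in% c(1L, 2L)])
  labels <- data.frame(
    kindred_id = kids,
    label = vapply(kids, function(k) {
      fi <- use[use$kindred_id == k, , drop = FALSE]
      label_inheritance(fi$gene, fi$zygosity, fi$category)
    }, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  list(findings = kf, labels = labels)
}

# Zygosity per member restricted to the shared variant keys.
.shared_zygosity <- function(fg, shared) {
  vapply(seq_len(nrow(fg)), function(i) {
    keys <- unlist(strsplit(fg$variant_keys[i], ",", fixed = TRUE))
    if (fg$zygosity[i] == "homozygous") return("homozygous")
    kept <- intersect(keys, shared)
    if (length(kept) >= 2L) "probable_compound_het" else "heterozygous"
  }, character(1))
}

#' Segregation consistency against unaffected relatives
#'
#' AR (homozygous) findings: an unaffected relative homozygous for a shared
#' variant marks the finding inconsistent. Probable compound het: an
#' unaffected relative carrying *all* member variants marks it
#' inconsistent. AD (heterozygous) findings assume full penetrance: an
#' unaffected carrier marks the finding inconsistent (flagged, not
#' discarded). With no genotyped unaffected relatives the finding is
#' `untestable`.
#'
#' @param zyg_class Shared zygosity class of the kindred finding.
#' @param shared_keys Character vector of shared variant keys.
#' @param unaffected_calls Calls data.frame restricted to the kindred's
#'   unaffected members.
#' @return `"consistent"`, `"inconsistent"` or `"untestable"`.
#' @export
check_segregation <- function(zyg_class, shared_keys, unaffected_calls) {
  if (is.null(unaffected_calls) || !nrow(unaffected_calls)) return("untestable")
  gt <- unaffected_calls[unaffected_calls$key %in% shared_keys &
                           unaffected_calls$genotype %in% c("het", "hom_alt"), ,
                         drop = FALSE]
  if (zyg_class == "homozygous") {
    if (any(gt$genotype == "hom_alt")) return("inconsistent")
  } else if (zyg_class == "probable_compound_het") {
    per <- split(gt$key, gt$sample_id)
    if (any(vapply(per, function(k) all(shared_keys %in% k), logical(1)))) {
      return("inconsistent")
    }
  } else {
    if (nrow(gt)) return("inconsistent")
  }
  "consistent"
}
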