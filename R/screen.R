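#' Tiered variant-prioritization screen of an annotated exome cohort
#'
#' The central pipeline. Per affected individual, calls carrying an
#' alternate allele are pushed through the five-stage filtering cascade
#' (quality, in-silico, rarity, synonymous/splice, ACMG; the rarity stage
#' iterates to a fixed point because its threshold depends on the gene's
#' zygosity class, which can change when a member variant is removed).
#' Surviving per-gene findings are routed through the three-tier category
#' screen (panel-1 with expected inheritance; panel-2 / unexpected
#' inheritance; homozygous forward screen in unlisted genes), flagged for
#' known other-phenotype genes, labeled with an inheritance mode, and
#' aggregated to kindred level for familial kindreds. Cohort-vs-gnomAD
#' enrichment is computed for every variant surviving the quality and
#' in-silico stages and adjusted batch-wise by Benjamini-Hochberg.
#'
#' @param calls Per-sample calls ([read_vcf()] layout).
#' @param annotations Variant annotations ([read_annotation_table()] layout).
#' @param pedigree Cohort metadata ([read_pedigree()] layout).
#' @param panel1 Category 1 gene panel (tiers + expected inheritance).
#' @param panel2 Category 2 curated gene panel.
#' @param cfg A [filter_config()].
#' @param other_phenotype_genes Genes whose homozygous findings likely
#'   explain a non-ovarian phenotype (flagged, not dropped).
#' @return Object of class `"poi_screen"`: a list with `findings`,
#'   `labels`, `kindred_findings`, `kindred_labels`, `enrichment`, `log`,
#'   plus the inputs needed by [summary.poi_screen()].
#' @seealso [summary.poi_screen()], [make_table_fixtures()],
#'   [generate_cohort()]
#' @export
poi_screen <- function(calls, annotations, pedigree, panel1, panel2,
                       cfg = filter_config(), other_phenotype_genes = character()) {
  check_panels(panel1, panel2)
  warns <- character()

  unknown <- setdiff(unique(calls$sample_id), pedigree$sample_id)
  if (length(unknown)) {
    msg <- paste0("sample(s) in calls absent from pedigree (records retained): ",
                  paste(unknown, collapse = ", "))
    warning(msg)
    warns <- c(warns, msg)
  }

  jn <- join_annotations(calls, annotations)
  ann <- jn$annotated
  affected_ids <- pedigree$sample_id[pedigree$affected]
  carrier <- ann[ann$genotype %in% c("het", "hom_alt") & ann$sample_id %in% affected_ids, ,
                 drop = FALSE]

  # Stages whose outcome does not depend on zygosity context.
  stage_rej <- c(quality = 0L, insilico = 0L, rarity = 0L,
                 synonymous_splice = 0L, acmg = 0L)
  if (nrow(carrier)) {
    sm <- .stage_matrix(carrier, cfg)
    for (s in colnames(sm)) stage_rej[s] <- stage_rej[s] + sum(!sm[, s])
    surv <- carrier[rowSums(!sm) == 0L, , drop = FALSE]
  } else {
    surv <- carrier
  }

  # Rarity fixed point: drop frequency failures, re-resolve zygosity,
  # repeat until stable (a compound-het pair losing a member falls back to
  # the stricter single-het threshold).
  repeat {
    if (!nrow(surv)) break
    grp <- interaction(surv$sample_id, surv$gene, drop = TRUE)
    zyg <- vapply(split(seq_len(nrow(surv)), grp), function(ix) {
      resolve_gene_zygosity(surv$genotype[ix], surv$key[ix])
    }, character(1))
    ctx <- rarity_context(zyg[as.character(grp)])
    bypass <- !is.na(surv$established_pathogenic) & surv$established_pathogenic
    ok <- bypass | passes_rarity(surv$gnomad_af, ctx, cfg)
    if (all(ok)) break
    stage_rej["rarity"] <- stage_rej["rarity"] + sum(!ok)
    surv <- surv[ok, , drop = FALSE]
  }

  surv <- .phase_collapse(surv, ann, pedigree, cfg, notes = environment())

  findings <- .build_findings(surv, pedigree, panel1, panel2)
  n_discarded <- attr(findings, "n_discarded")
  findings <- flag_other_phenotype(findings, other_phenotype_genes)

  labels <- .label_individuals(findings, affected_ids)
  kin <- aggregate_kindred(findings, calls = ann, pedigree = pedigree,
                           panel1 = panel1, panel2 = panel2,
                           other_phenotype_genes = other_phenotype_genes)

  enrichment <- .cohort_enrichment(carrier, pedigree, cfg)

  log <- list(
    config = unclass(cfg),
    n_calls = nrow(calls),
    n_annotated = nrow(ann),
    n_unannotated = nrow(jn$unannotated),
    n_carrier_calls = nrow(carrier),
    stage_rejections = as.list(stage_rej),
    n_filter_passed_calls = nrow(surv),
    pass_counts = list(
      category1 = sum(findings$category == 1L),
      category2 = sum(findings$category == 2L),
      category3 = sum(findings$category == 3L)
    ),
    n_discarded_unlisted_nonhomozygous = n_discarded,
    enrichment_family_size = nrow(enrichment),
    warnings = warns
  )

  structure(list(findings = findings, labels = labels,
                 kindred_findings = kin$findings, kindred_labels = kin$labels,
                 enrichment = enrichment, log = log,
                 pedigree = pedigree, config = cfg,
                 other_phenotype_genes = other_phenotype_genes),
            class = "poi_screen")
}

# Collapse a probable compound het proven cis by parental genotypes to a
# single heterozygous finding keeping the lower-frequency member. Proof of
# cis: one genotyped parent carries every member variant and the other
# genotyped parent carries none.
.phase_collapse <- function(surv, all_calls, pedigree, cfg, notes) {
  if (!nrow(surv)) return(surv)
  drop_idx <- integer()
  grp <- split(seq_len(nrow(surv)), interaction(surv$sample_id, surv$gene, drop = TRUE))
  for (ix in grp) {
    if (length(ix) < 2L || any(surv$genotype[ix] == "hom_alt")) next
    sid <- surv$sample_id[ix[1L]]
    prow <- pedigree[pedigree$sample_id == sid, , drop = FALSE]
    if (!nrow(prow)) next
    parents <- setdiff(c(prow$father_id, prow$mother_id), c("0", ""))
    parents <- parents[parents %in% all_calls$sample_id]
    if (length(parents) != 2L) next
    keys <- surv$key[ix]
    carries <- vapply(parents, function(p) {
      pc <- all_calls[all_calls$sample_id == p & all_calls$key %in% keys &
                        all_calls$genotype %in% c("het", "hom_alt"), , drop = FALSE]
      length(unique(pc$key))
    }, integer(1))
    if (any(carries == length(keys)) && any(carries == 0L)) {
      af <- surv$gnomad_af[ix]
      af[is.na(af)] <- 0
      keep <- ix[which.min(af)]
      extra <- setdiff(ix, keep)
      # survivor is now a lone het: re-check the stricter threshold
      if (!isTRUE(surv$established_pathogenic[keep]) &&
          !passes_rarity(surv$gnomad_af[keep], "monoallelic", cfg)) {
        extra <- ix
      }
      drop_idx <- c(drop_idx, extra)
    }
  }
  if (length(drop_idx)) surv <- surv[-drop_idx, , drop = FALSE]
  surv
}

# Per sample x gene: zygosity, category routing, tier; unlisted
# non-homozygous groups are discarded (counted via attribute).
.build_findings <- function(surv, pedigree, panel1, panel2) {
  empty <- data.frame(sample_id = character(), kindred_id = character(),
                      gene = character(), variant_keys = character(),
                      n_variants = integer(), zygosity = character(),
                      category = integer(), tier = character(),
                      reroute_reason = character(), stringsAsFactors = FALSE)
  if (!nrow(surv)) {
    attr(empty, "n_discarded") <- 0L
    return(empty)
  }
  grp <- split(seq_len(nrow(surv)), interaction(surv$sample_id, surv$gene, drop = TRUE))
  rows <- lapply(grp, function(ix) {
    sid <- surv$sample_id[ix[1L]]
    gene <- surv$gene[ix[1L]]
    zyg <- resolve_gene_zygosity(surv$genotype[ix], surv$key[ix])
    cl <- classify_finding(gene, zyg, panel1, panel2)
    data.frame(sample_id = sid,
               kindred_id = pedigree$kindred_id[match(sid, pedigree$sample_id)],
               gene = gene,
               variant_keys = paste(sort(unique(surv$key[ix])), collapse = ","),
               n_variants = length(unique(surv$key[ix])),
               zygosity = zyg, category = cl$category, tier = cl$tier,
               reroute_reason = cl$reroute_reason, stringsAsFactors = FALSE)
  })
  f <- do.call(rbind, rows)
  n_discarded <- sum(is.na(f$category))
  f <- f[!is.na(f$category), , drop = FALSE]
  f <- f[order(f$sample_id, f$gene), , drop = FALSE]
  rownames(f) <- NULL
  attr(f, "n_discarded") <- n_discarded
  f
}

# One inheritance label per affected individual with >= 1 Category 1/2
# finding; other-phenotype-flagged findings do not contribute.
.label_individuals <- function(findings, affected_ids) {
  use <- findings[!findings$other_phenotype_flag, , drop = FALSE]
  ids <- intersect(affected_ids, unique(use$sample_id[use$category %in% c(1L, 2L)]))
  lab <- vapply(ids, function(sid) {
    fi <- use[use$sample_id == sid, , drop = FALSE]
    label_inheritance(fi$gene, fi$zygosity, fi$category)
  }, character(1))
  data.frame(sample_id = ids, label = unname(lab), stringsAsFactors = FALSE)
}

# Enrichment family: variants surviving the quality + in-silico stages
# (annotated population counts required).
.cohort_enrichment <- function(carrier, pedigree, cfg) {
  empty <- data.frame(variant_key = character(), cohort_ac = integer(),
                      cohort_an = integer(), pop_ac = numeric(), pop_an = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!nrow(carrier)) return(empty)
  keep <- passes_quality(carrier$qual, carrier$depth, cfg) &
    ((!is.na(carrier$established_pathogenic) & carrier$established_pathogenic) |
       insilico_deleterious(carrier$cadd, carrier$polyphen_damaging,
                            carrier$sift_deleterious, FALSE, cfg))
  cc <- carrier[keep, , drop = FALSE]
  cc <- cc[!is.na(cc$gnomad_ac) & !is.na(cc$gnomad_an) & cc$gnomad_an > 0, , drop = FALSE]
  if (!nrow(cc)) return(empty)
  an <- 2L * sum(pedigree$affected)
  per_key <- split(seq_len(nrow(cc)), cc$key)
  keys <- names(per_key)
  ac <- vapply(per_key, function(ix) {
    sum(ifelse(cc$genotype[ix] == "hom_alt", 2L, 1L))
  }, integer(1))
  pop_ac <- vapply(per_key, function(ix) cc$gnomad_ac[ix[1L]], numeric(1))
  pop_an <- vapply(per_key, function(ix) cc$gnomad_an[ix[1L]], numeric(1))
  res <- variant_enrichment(keys, unname(ac), rep(an, length(keys)),
                            unname(pop_ac), unname(pop_an), cfg)
  res[order(res$variant_key), , drop = FALSE]
}

#' Run the three-pass tiered screen
#'
#' Module-surface wrapper around [poi_screen()] exposing the screen as the
#' three ordered passes (Category 1, then Category 2 cohort-wide including
#' individuals already carrying a Category 1 finding, then the cohort-wide
#' Category 3 homozygous forward screen). Individuals accumulate findings
#' across passes; per-pass counts are in the run log.
#'
#' @inheritParams poi_screen
#' @return The `"poi_screen"` object.
#' @export
run_tiered_screen <- function(calls, annotations, pedigree, panel1, panel2,
                              cfg = filter_config(),
                              other_phenotype_genes = character()) {
  poi_screen(calls, annotations, pedigree, panel1, panel2, cfg,
             other_phenotype_genes)
}

#' @export
print.poi_screen <- function(x, ...) {
  cat("Tiered POI exome screen\n")
  cat(sprintf("  individuals in pedigree : %d (%d affected)\n",
              nrow(x$pedigree), sum(x$pedigree$affected)))
  cat(sprintf("  filter-passed findings  : %d (cat1 %d, cat2 %d, cat3 %d)\n",
              nrow(x$findings), x$log$pass_counts$category1,
              x$log$pass_counts$category2, x$log$pass_counts$category3))
  cat(sprintf("  individuals labeled     : %d\n", nrow(x$labels)))
  cat(sprintf("  kindred-level findings  : %d\n", nrow(x$kindred_findings)))
  cat("  (use summary() for cohort detection rates)\n")
  invisible(x)
}
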