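#' Published-table fixtures: familial, sporadic and candidate-gene tables
#'
#' Expands the plain-text encodings of the published variant tables
#' (shipped under `inst/extdata/`) into complete pipeline inputs: annotated
#' calls, pedigree, gene panels and the other-phenotype gene list, so that
#' running the cascade, the three-pass screen and kindred aggregation
#' reproduces every printed row and every printed detection-rate statistic
#' offline.
#'
#' The familial table covers 17 kindreds (31 recruited affected women; 6
#' kindreds finding-free), the sporadic table 118 individuals (rows for 77;
#' 41 finding-free). Zygosity "Biallelic" expands to a homozygous call,
#' "Monoallelic" to a heterozygous call; two monoallelic variants in one
#' gene form a probable compound het. Synthetic genomic coordinates are
#' assigned deterministically per gene (the pipeline never needs real
#' coordinates); population frequencies are the literal printed gnomAD v4
#' values. Rows whose printed frequency meets or exceeds their
#' zygosity-context threshold carry the established-POI allowlist flag --
#' these are variants in established POI genes that the published cascade
#' retained although their population frequency exceeds the printed
#' threshold, which the retention rule's "well-established relationship"
#' clause permits.
#'
#' @return A list with elements `familial`, `sporadic`, `combined` (each a
#'   list of `calls`, `annotations`, `pedigree`), `panel1`, `panel2`,
#'   `other_phenotype_genes`, `candidates` (the candidate-gene counting
#'   table) and `printed` (per-row printed category and per-entity printed
#'   inheritance labels, for verification).
#' @export
make_table_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "tierpoi", mustWork = TRUE)
  t2 <- utils::read.table(ext("table2_familial.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  t3 <- utils::read.table(ext("table3_sporadic.tsv"), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  panel1 <- read_gene_panel(ext("panel1.tsv"))
  panel2 <- read_gene_panel(ext("panel2.tsv"))
  other <- utils::read.table(ext("other_phenotype_genes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  candidates <- utils::read.table(ext("table4_candidates.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)

  t2$cohort <- "familial"; t3$cohort <- "sporadic"
  rows <- rbind(t2, t3)

  # Deterministic synthetic coordinates: one contig block per gene, one
  # position per distinct (gene, hgvs_c).
  genes <- sort(unique(rows$gene))
  gi <- match(rows$gene, genes)
  vid <- paste(rows$gene, rows$hgvs_c, sep = "|")
  uu <- unique(data.frame(vid = vid, gene = rows$gene, hgvs_c = rows$hgvs_c,
                          stringsAsFactors = FALSE))
  uu$rank <- stats::ave(seq_len(nrow(uu)), uu$gene, FUN = seq_along)
  rows$chrom <- paste0("chr", (gi - 1L) %% 22L + 1L)
  rows$pos <- match(rows$gene, genes) * 100000L + uu$rank[match(vid, uu$vid)] * 100L

  snv <- regmatches(rows$hgvs_c, regexec("([ACGT])>([ACGT])$", rows$hgvs_c))
  rows$ref <- vapply(snv, function(m) if (length(m)) m[2] else "CA", character(1))
  rows$alt <- vapply(snv, function(m) if (length(m)) m[3] else "C", character(1))
  rows$key <- variant_key(rows$chrom, rows$pos, rows$ref, rows$alt)

  # Zygosity context per printed sample x gene group (a biallelic row or a
  # two-het pair takes the biallelic threshold).
  grp <- paste(rows$sample, rows$gene, sep = "|")
  n_in_gene <- stats::ave(seq_along(grp), grp, FUN = length)
  biallelic_ctx <- stats::ave(rows$zygosity == "Biallelic", grp, FUN = any) |
    n_in_gene >= 2L
  cfg <- filter_config()
  thr <- ifelse(biallelic_ctx, cfg$maf_biallelic, cfg$maf_monoallelic)
  af <- rows$af
  rows$established <- !is.na(af) & af >= thr
  # the flag is a variant-level annotation: any qualifying usage sets it
  rows$established <- as.logical(stats::ave(rows$established, vid, FUN = any))

  an_pop <- 1614000
  uniq <- rows[!duplicated(rows$key), , drop = FALSE]
  annotations <- data.frame(
    chrom = uniq$chrom, pos = uniq$pos, ref = uniq$ref, alt = uniq$alt,
    gene = uniq$gene, transcript = uniq$transcript, hgvs_c = uniq$hgvs_c,
    hgvs_p = ifelse(is.na(uniq$hgvs_p), "", uniq$hgvs_p),
    consequence = uniq$consequence, intron_offset = uniq$intron_offset,
    gnomad_af = uniq$af,
    gnomad_ac = ifelse(is.na(uniq$af), NA_real_, round(uniq$af * an_pop)),
    gnomad_an = ifelse(is.na(uniq$af), NA_real_, an_pop),
    cadd = 25,
    polyphen_damaging = TRUE, sift_deleterious = TRUE,
    acmg_class = ifelse(uniq$consequence %in% c("stop_gain", "frameshift"), "P", "LP"),
    splice_loss_predicted = uniq$consequence %in% c("splice_site", "intronic"),
    established_pathogenic = uniq$established,
    stringsAsFactors = FALSE)
  annotations$key <- variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt)
  annotations <- validate_annotations(annotations)

  ped_fam <- .familial_pedigree()
  ped_spo <- .sporadic_pedigree()

  calls_for <- function(tab, members_of) {
    rws <- lapply(seq_len(nrow(tab)), function(i) {
      for_samples <- members_of(tab$sample[i])
      data.frame(chrom = tab$chrom[i], pos = tab$pos[i], ref = tab$ref[i],
                 alt = tab$alt[i], key = tab$key[i], sample_id = for_samples,
                 genotype = if (tab$zygosity[i] == "Biallelic") "hom_alt" else "het",
                 qual = 99, depth = 75, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rws)
    rownames(out) <- NULL
    out
  }
  fam_rows <- rows[rows$cohort == "familial", , drop = FALSE]
  spo_rows <- rows[rows$cohort == "sporadic", , drop = FALSE]
  fam_calls <- calls_for(fam_rows, function(kid) {
    ped_fam$sample_id[ped_fam$kindred_id == kid & ped_fam$affected]
  })
  spo_calls <- calls_for(spo_rows, function(sid) sid)

  printed <- list(
    table2 = fam_rows[, c("sample", "gene", "zygosity", "inheritance",
                          "row_category", "tier", "af", "key")],
    table3 = spo_rows[, c("sample", "gene", "zygosity", "inheritance",
                          "row_category", "tier", "af", "key")]
  )

  comb_ped <- rbind(ped_fam, ped_spo)
  list(
    familial = list(calls = fam_calls, annotations = annotations, pedigree = ped_fam),
    sporadic = list(calls = spo_calls, annotations = annotations, pedigree = ped_spo),
    combined = list(calls = rbind(fam_calls, spo_calls), annotations = annotations,
                    pedigree = comb_ped),
    panel1 = panel1, panel2 = panel2,
    other_phenotype_genes = other,
    candidates = candidates,
    printed = printed
  )
}

# 17 familial kindreds, 31 recruited affected women (two per kindred except
# FPOI10, FPOI11 and FPOI17, which link to unrecruited affected relatives);
# 8 kindreds consanguineous. Members are <kindred>_1 / <kindred>_2.
.familial_pedigree <- function() {
  kindreds <- paste0("FPOI", 1:17)
  two_member <- setdiff(kindreds, c("FPOI10", "FPOI11", "FPOI17"))
  consang <- c("FPOI1", "FPOI2", "FPOI3", "FPOI5", "FPOI6", "FPOI8", "FPOI11",
               "FPOI12")
  rows <- lapply(kindreds, function(k) {
    n <- if (k %in% two_member) 2L else 1L
    data.frame(sample_id = paste0(k, "_", seq_len(n)), kindred_id = k,
               father_id = "0", mother_id = "0", sex = "2",
               affected = TRUE, subcohort = "familial",
               consanguineous = k %in% consang, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# 118 sporadic individuals, each her own kindred; consanguinity as printed.
.sporadic_pedigree <- function() {
  ids <- paste0("SPOI", 1:118)
  data.frame(sample_id = ids, kindred_id = ids, father_id = "0", mother_id = "0",
             sex = "2", affected = TRUE, subcohort = "sporadic",
             consanguineous = ids %in% c("SPOI4", "SPOI17", "SPOI25", "SPOI77"),
             stringsAsFactors = FALSE)
}

#' Map a printed inheritance-pattern token to the package label
#'
#' `"Polygenic"` and `"Oligogenic"` both map to `"oligogenic"`; `AR`, `AD`
#' and `CH` map to themselves.
#'
#' @param x Printed token(s).
#' @return Package label(s).
#' @export
printed_label <- function(x) {
  out <- ifelse(x %in% c("Polygenic", "Oligogenic"), "oligogenic", x)
  out[!out %in% c("AR", "AD", "CH", "oligogenic")] <- NA_character_
  out
}
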