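#' Build a canonical variant key
#'
#' Variant identity throughout the package is the exact tuple
#' (chrom, pos, ref, alt), rendered as `"chrom:pos:ref:alt"`.
#'
#' @param chrom,pos,ref,alt Vectors describing the variant allele.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.genotype_levels <- c("het", "hom_alt", "hom_ref", "missing")
.consequence_levels <- c("missense", "stop_gain", "frameshift", "inframe_indel",
                         "splice_site", "synonymous", "intronic", "utr", "other")
.acmg_levels <- c("P", "LP", "VUS", "LB", "B")

#' Read a (possibly multi-sample, multi-allelic) VCF into per-sample calls
#'
#' Every record is decomposed into one row per sample per ALT allele.
#' Diploid genotypes containing the alt allele twice map to `hom_alt`, once
#' to `het`, zero times to `hom_ref`; genotypes with missing alleles map to
#' `missing`. Ploidy other than 2 is treated as `missing` with a warning
#' (the cohort is 46,XX, so no hemizygous rule is needed). Positions stay
#' 1-based as in the VCF.
#'
#' @param path Path to a VCF v4.x file (plain or bgzipped).
#' @return A data.frame with columns `chrom, pos, ref, alt, key, sample_id,
#'   genotype, qual, depth`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), key = character(), sample_id = character(),
                      genotype = character(), qual = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE))
  }
  has_gt <- !is.null(v@gt) && ncol(v@gt) > 1L
  if (!has_gt) stop("malformed VCF '", path, "': no sample genotype columns")
  samples <- colnames(v@gt)[-1L]
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
                 error = function(e) NULL)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  out <- vector("list", n_rec)
  odd_ploidy <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    alts <- alts[!is.na(alts) & alts != "." & alts != ""]
    if (!length(alts)) next
    per_sample <- lapply(samples, function(s) {
      g <- gt[i, s]
      alleles <- if (is.na(g) || g == "") NA_character_ else strsplit(g, "[/|]")[[1L]]
      geno <- character(length(alts))
      if (length(alleles) == 1L && is.na(alleles[1L])) {
        geno[] <- "missing"
      } else if (length(alleles) != 2L) {
        odd_ploidy <<- odd_ploidy + 1L
        geno[] <- "missing"
      } else if (any(alleles == "." | is.na(alleles))) {
        geno[] <- "missing"
      } else {
        ia <- suppressWarnings(as.integer(alleles))
        if (any(is.na(ia))) stop("malformed VCF '", path, "': bad genotype '", g,
                                 "' at record ", i)
        for (k in seq_along(alts)) {
          cnt <- sum(ia == k)
          geno[k] <- if (cnt == 2L) "hom_alt" else if (cnt == 1L) "het" else "hom_ref"
        }
      }
      data.frame(alt = alts, sample_id = s, genotype = geno, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, per_sample)
    block$chrom <- fix[i, "CHROM"]
    block$pos <- as.integer(fix[i, "POS"])
    block$ref <- fix[i, "REF"]
    block$qual <- qual[i]
    block$depth <- if (is.null(dp)) NA_real_ else dp[i, block$sample_id]
    out[[i]] <- block
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (odd_ploidy > 0L) {
    warning(odd_ploidy, " genotype(s) with ploidy != 2 treated as missing")
  }
  calls$key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  rownames(calls) <- NULL
  calls[, c("chrom", "pos", "ref", "alt", "key", "sample_id", "genotype", "qual", "depth")]
}

#' Write per-sample calls as a multi-sample VCF
#'
#' The inverse convenience of [read_vcf()] for synthetic cohorts: one record
#' per variant key, `GT:DP` per sample, `QUAL` shared across samples.
#'
#' @param calls Data.frame as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  samples <- sort(unique(calls$sample_id))
  vars <- unique(calls[, c("chrom", "pos", "ref", "alt", "key", "qual")])
  vars <- vars[order(vars$chrom, vars$pos, vars$alt), , drop = FALSE]
  gt_of <- c(het = "0/1", hom_alt = "1/1", hom_ref = "0/0", missing = "./.")
  idx <- split(seq_len(nrow(calls)), calls$key)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vars)), function(i) {
    rows <- calls[idx[[vars$key[i]]], , drop = FALSE]
    m <- match(samples, rows$sample_id)
    geno <- ifelse(is.na(m), "0/0", gt_of[rows$genotype[m]])
    dpv <- ifelse(is.na(m), "30", ifelse(is.na(rows$depth[m]), ".",
                                         as.character(rows$depth[m])))
    paste(c(vars$chrom[i], vars$pos[i], ".", vars$ref[i], vars$alt[i],
            ifelse(is.na(vars$qual[i]), ".", vars$qual[i]), "PASS", ".", "GT:DP",
            paste(geno, dpv, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read an extended PED-like pedigree/cohort-metadata file
#'
#' Whitespace-delimited, 8 columns, with header allowed:
#' `kindred_id sample_id father_id mother_id sex affected subcohort
#' consanguineous`. `affected` uses PED coding (2 = affected, 1 =
#' unaffected); `subcohort` is one of `familial`, `sporadic`, `relative`;
#' `consanguineous` is 0/1. Parent ids must be `0` or resolve to another row
#' (unresolved ids are kept as declared-external with a warning).
#'
#' @param path Path to the pedigree file.
#' @return Data.frame with columns `sample_id, kindred_id, father_id,
#'   mother_id, sex, affected, subcohort, consanguineous`.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("kindred", first, ignore.case = TRUE)
  ped <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 8L) stop("pedigree file must have 8 columns, found ", ncol(ped))
  names(ped) <- c("kindred_id", "sample_id", "father_id", "mother_id", "sex",
                  "affected", "subcohort", "consanguineous")
  if (anyDuplicated(ped$sample_id)) {
    stop("duplicate sample_id in pedigree: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(ped$subcohort), c("familial", "sporadic", "relative"))
  if (length(bad)) stop("unknown subcohort token(s): ", paste(bad, collapse = ", "))
  ped$affected <- ped$affected == "2"
  ped$consanguineous <- ped$consanguineous %in% c("1", "TRUE")
  for (col in c("father_id", "mother_id")) {
    ref <- ped[[col]]
    unresolved <- setdiff(ref[ref != "0" & ref != ""], ped$sample_id)
    if (length(unresolved)) {
      warning("parent id(s) not in pedigree, treated as external: ",
              paste(unresolved, collapse = ", "))
    }
  }
  ped[, c("sample_id", "kindred_id", "father_id", "mother_id", "sex",
          "affected", "subcohort", "consanguineous")]
}

#' Read a gene panel file
#'
#' Tab-separated with header `gene category tier expected_inheritance`
#' (an optional `source_note` column is carried through). `tier` must be
#' `green`/`amber`/`red` for Category 1 entries and `none` for Category 2;
#' `expected_inheritance` is `biallelic`, `monoallelic` or
#' `biallelic|monoallelic` and must be non-empty for Category 1 entries.
#'
#' @param path Path to the panel TSV.
#' @return Data.frame with one row per gene.
#' @export
read_gene_panel <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("gene", "category", "tier", "expected_inheritance")
  if (!all(required %in% names(p))) {
    stop("panel file must have columns: ", paste(required, collapse = ", "))
  }
  if (!"source_note" %in% names(p)) p$source_note <- ""
  p$category <- as.integer(p$category)
  p <- unique(p[, c("gene", "category", "tier", "expected_inheritance", "source_note")])
  if (anyDuplicated(p$gene)) {
    stop("duplicate panel gene(s) with conflicting entries: ",
         paste(unique(p$gene[duplicated(p$gene)]), collapse = ", "))
  }
  if (!all(p$category %in% c(1L, 2L))) stop("panel category must be 1 or 2")
  if (!all(p$tier %in% c("green", "amber", "red", "none"))) {
    stop("panel tier must be green/amber/red/none")
  }
  if (any(p$category == 1L & p$tier == "none")) stop("Category 1 entries must carry a tier")
  if (any(p$category == 2L & p$tier != "none")) stop("Category 2 entries must have tier 'none'")
  modes <- strsplit(p$expected_inheritance, "[|,]")
  ok <- vapply(modes, function(m) length(m) >= 1L &&
                 all(m %in% c("biallelic", "monoallelic")), logical(1))
  if (any(p$category == 1L & !ok)) {
    stop("Category 1 entries need expected_inheritance in {biallelic, monoallelic}")
  }
  p
}

#' Check that the two panels do not overlap
#'
#' @param panel1,panel2 Panels read by [read_gene_panel()].
#' @return Invisibly `TRUE`; errors on any gene present in both panels.
#' @export
check_panels <- function(panel1, panel2) {
  both <- intersect(panel1$gene, panel2$gene)
  if (length(both)) {
    stop("gene(s) on both panels: ", paste(both, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a pre-annotated variant table
#'
#' Tab-separated, one row per variant allele, keyed by (chrom,pos,ref,alt).
#' Carries functional annotation (gene, transcript, HGVS, consequence,
#' intron offset), gnomAD v4-style population frequency and allele counts,
#' in-silico verdicts (CADD, PolyPhen2, SIFT), ACMG class, a splice-loss
#' prediction, and the established-POI allowlist flag.
#'
#' @param path Path to the annotation TSV.
#' @return Data.frame of annotations with a `key` column.
#' @export
read_annotation_table <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  required <- c("chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c",
                "hgvs_p", "consequence", "intron_offset", "gnomad_af", "gnomad_ac",
                "gnomad_an", "cadd", "polyphen_damaging", "sift_deleterious",
                "acmg_class", "splice_loss_predicted", "established_pathogenic")
  missing_cols <- setdiff(required, names(a))
  if (length(missing_cols)) {
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  a$key <- variant_key(a$chrom, a$pos, a$ref, a$alt)
  validate_annotations(a)
}

#' Validate an annotation data.frame
#'
#' Enforces the annotation invariants: unique keys, frequencies in `[0,1]`
#' consistent with `ac/an`, known consequence and ACMG tokens, and
#' `intron_offset == 0` exactly for non-intronic consequences.
#'
#' @param a Annotation data.frame with a `key` column.
#' @return `a`, with logical/numeric columns coerced.
#' @export
validate_annotations <- function(a) {
  if (anyDuplicated(a$key)) {
    stop("duplicate annotation key(s): ",
         paste(unique(a$key[duplicated(a$key)]), collapse = ", "))
  }
  a$pos <- as.integer(a$pos)
  a$intron_offset <- as.integer(a$intron_offset)
  for (col in c("gnomad_af", "gnomad_ac", "gnomad_an", "cadd")) {
    a[[col]] <- as.numeric(a[[col]])
  }
  for (col in c("polyphen_damaging", "sift_deleterious", "splice_loss_predicted",
                "established_pathogenic")) {
    a[[col]] <- as.logical(a[[col]])
  }
  a$established_pathogenic[is.na(a$established_pathogenic)] <- FALSE
  if (any(a$pos < 1L)) stop("annotation pos must be >= 1")
  if (any(a$ref == a$alt)) stop("annotation ref must differ from alt")
  af <- a$gnomad_af
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("gnomad_af must lie in [0, 1]")
  both <- !is.na(a$gnomad_ac) & !is.na(a$gnomad_an)
  if (any(both & a$gnomad_ac > a$gnomad_an)) stop("gnomad_ac must not exceed gnomad_an")
  chk <- both & !is.na(af) & a$gnomad_an > 0
  if (any(abs(af[chk] - a$gnomad_ac[chk] / a$gnomad_an[chk]) > 1 / pmax(a$gnomad_an[chk], 1) + 1e-9)) {
    stop("gnomad_af inconsistent with gnomad_ac/gnomad_an beyond rounding")
  }
  if (!all(a$consequence %in% .consequence_levels)) {
    stop("unknown consequence token(s): ",
         paste(setdiff(unique(a$consequence), .consequence_levels), collapse = ", "))
  }
  acmg_ok <- is.na(a$acmg_class) | a$acmg_class %in% .acmg_levels
  if (!all(acmg_ok)) {
    stop("unknown acmg_class token(s): ",
         paste(unique(a$acmg_class[!acmg_ok]), collapse = ", "))
  }
  intronish <- a$consequence %in% c("intronic", "splice_site")
  if (any(!intronish & a$intron_offset != 0L) || any(intronish & a$intron_offset == 0L)) {
    stop("intron_offset must be 0 exactly for non-intronic/splice consequences")
  }
  a
}

#' Join per-sample calls to variant annotations
#'
#' Exact join on the (chrom,pos,ref,alt) key. Calls without a matching
#' annotation are routed to the `unannotated` sink (counted in the run log),
#' never silently dropped.
#'
#' @param calls Calls data.frame from [read_vcf()].
#' @param annotations Annotation data.frame from [read_annotation_table()].
#' @return List with `annotated` (calls + annotation columns) and
#'   `unannotated` (the sink rows).
#' @export
join_annotations <- function(calls, annotations) {
  m <- match(calls$key, annotations$key)
  sink <- calls[is.na(m), , drop = FALSE]
  hit <- calls[!is.na(m), , drop = FALSE]
  ann_cols <- setdiff(names(annotations), c("chrom", "pos", "ref", "alt", "key"))
  joined <- cbind(hit, annotations[m[!is.na(m)], ann_cols, drop = FALSE])
  rownames(joined) <- NULL
  list(annotated = joined, unannotated = sink)
}

#' Write / read a findings table
#'
#' Findings reports are plain TSVs and round-trip field-for-field through
#' these two functions.
#'
#' @param findings Findings data.frame (see [poi_screen()]).
#' @param path Output path.
#' @return `write_findings()`: `path`, invisibly. `read_findings()`: the
#'   findings data.frame.
#' @export
write_findings <- function(findings, path) {
  utils::write.table(findings, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_findings
#' @export
read_findings <- function(path) {
  f <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "NA")
  if ("other_phenotype_flag" %in% names(f)) {
    f$other_phenotype_flag <- as.logical(f$other_phenotype_flag)
  }
  f
}

#' Write a run log as JSON
#'
#' @param log Run-log list (config snapshot, per-stage rejection counts,
#'   per-pass finding counts, warnings, seed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
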