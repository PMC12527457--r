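#' Synthetic-cohort simulation configuration
#'
#' Defines the study conditions the generator emulates: 118 sporadic
#' individuals and 17 familial kindreds (two recruited affected sisters
#' each by default), 8/17 kindreds consanguineous, and per-entity planted
#' finding compositions mirroring the observed cohort proportions.
#' Decoy counts give, per affected individual, the number of variants
#' constructed to violate exactly one named cascade stage while passing
#' all others.
#'
#' @param n_sporadic Number of sporadic probands.
#' @param n_familial_kindreds Number of familial kindreds.
#' @param kindred_size Recruited affected members per familial kindred.
#' @param consanguineous_fraction Fraction of familial kindreds flagged
#'   consanguineous (these preferentially receive autosomal-recessive
#'   plants).
#' @param composition_sporadic,composition_familial Named probability
#'   vectors over the plant types `cat1_AR, cat1_AD, cat1_CH, cat2_AD,
#'   cat2_CH, oligogenic, cat3_hom, other_phenotype_hom, no_finding`
#'   (must sum to 1).
#' @param decoys_per_individual Named nonnegative integer vector over the
#'   cascade stages `quality, insilico, rarity, synonymous_splice, acmg`.
#' @param an_population gnomAD-scale allele number used for synthetic
#'   population counts.
#' @param seed Integer random seed; identical seed + config give
#'   byte-identical outputs.
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(n_sporadic = 118,
                              n_familial_kindreds = 17,
                              kindred_size = 2,
                              consanguineous_fraction = 8 / 17,
                              composition_sporadic = c(
                                cat1_AR = 5, cat1_AD = 14, cat1_CH = 3,
                                cat2_AD = 34, cat2_CH = 1, oligogenic = 26,
                                cat3_hom = 2, other_phenotype_hom = 1,
                                no_finding = 32) / 118,
                              composition_familial = c(
                                cat1_AR = 5, cat1_AD = 0, cat1_CH = 0,
                                cat2_AD = 3, cat2_CH = 1, oligogenic = 2,
                                cat3_hom = 0, other_phenotype_hom = 0,
                                no_finding = 6) / 17,
                              decoys_per_individual = c(
                                quality = 1, insilico = 1, rarity = 1,
                                synonymous_splice = 1, acmg = 1),
                              an_population = 1614000,
                              seed = 1) {
  plant_types <- c("cat1_AR", "cat1_AD", "cat1_CH", "cat2_AD", "cat2_CH",
                   "oligogenic", "cat3_hom", "other_phenotype_hom", "no_finding")
  stopifnot(setequal(names(composition_sporadic), plant_types),
            setequal(names(composition_familial), plant_types),
            abs(sum(composition_sporadic) - 1) < 1e-9,
            abs(sum(composition_familial) - 1) < 1e-9,
            all(decoys_per_individual >= 0))
  stages <- c("quality", "insilico", "rarity", "synonymous_splice", "acmg")
  stopifnot(setequal(names(decoys_per_individual), stages))
  structure(list(n_sporadic = n_sporadic,
                 n_familial_kindreds = n_familial_kindreds,
                 kindred_size = kindred_size,
                 consanguineous_fraction = consanguineous_fraction,
                 composition_sporadic = composition_sporadic[plant_types],
                 composition_familial = composition_familial[plant_types],
                 decoys_per_individual = decoys_per_individual[stages],
                 an_population = an_population,
                 seed = seed),
            class = "simulation_config")
}

# Synthetic gene universe: invented symbols and coordinates (the pipeline
# never needs real ones).
.sim_universe <- function() {
  p1 <- data.frame(
    gene = sprintf("P1G%02d", 1:20), category = 1L,
    tier = rep(c("green", "amber", "red"), c(8, 6, 6)),
    expected_inheritance = rep(c("biallelic", "monoallelic", "biallelic|monoallelic"),
                               c(8, 8, 4)),
    source_note = "synthetic panel-1 gene", stringsAsFactors = FALSE)
  p2 <- data.frame(
    gene = sprintf("P2G%02d", 1:40), category = 2L, tier = "none",
    expected_inheritance = "biallelic|monoallelic",
    source_note = "synthetic panel-2 gene", stringsAsFactors = FALSE)
  list(panel1 = p1, panel2 = p2,
       candidates = sprintf("CAND%02d", 1:30),
       other_phenotype = sprintf("OPHEN%02d", 1:5),
       decoy = sprintf("DECOY%02d", 1:60))
}

#' Generate a fully self-contained synthetic cohort
#'
#' Plants findings per entity according to the composition (familial plants
#' are shared by every affected kindred member; consanguineous kindreds
#' draw from a composition with tripled autosomal-recessive weight), plus
#' per-individual decoy variants each violating exactly one named cascade
#' stage. Planted variants satisfy every filter by construction
#' (quality >= 20, depth >= 10, >= 2 in-silico votes, stratum-appropriate
#' gnomAD frequency, P/LP class). Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `"poi_cohort_bundle"`: `calls, annotations,
#'   pedigree, panel1, panel2, other_phenotype_genes, manifest, decoys,
#'   config`.
#' @export
generate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  uni <- .sim_universe()
  plant_types <- names(cfg$composition_sporadic)

  # pedigree ------------------------------------------------------------
  spo_ids <- sprintf("SS%03d", seq_len(cfg$n_sporadic))
  kin_ids <- sprintf("FK%02d", seq_len(cfg$n_familial_kindreds))
  n_consang <- round(cfg$consanguineous_fraction * cfg$n_familial_kindreds)
  consang <- kin_ids %in% kin_ids[seq_len(n_consang)]
  fam_members <- lapply(kin_ids, function(k) paste0(k, "_", seq_len(cfg$kindred_size)))
  pedigree <- rbind(
    data.frame(sample_id = spo_ids, kindred_id = spo_ids, father_id = "0",
               mother_id = "0", sex = "2", affected = TRUE, subcohort = "sporadic",
               consanguineous = FALSE, stringsAsFactors = FALSE),
    do.call(rbind, lapply(seq_along(kin_ids), function(i) {
      data.frame(sample_id = fam_members[[i]], kindred_id = kin_ids[i],
                 father_id = "0", mother_id = "0", sex = "2", affected = TRUE,
                 subcohort = "familial", consanguineous = consang[i],
                 stringsAsFactors = FALSE)
    })))

  # entity plans ---------------------------------------------------------
  spo_plan <- sample(plant_types, cfg$n_sporadic, replace = TRUE,
                     prob = cfg$composition_sporadic)
  fam_comp_consang <- cfg$composition_familial
  fam_comp_consang["cat1_AR"] <- fam_comp_consang["cat1_AR"] * 3
  fam_comp_consang <- fam_comp_consang / sum(fam_comp_consang)
  fam_plan <- vapply(seq_along(kin_ids), function(i) {
    comp <- if (consang[i]) fam_comp_consang else cfg$composition_familial
    sample(plant_types, 1, prob = comp)
  }, character(1))

  # gene pools per plant role
  p1_bi <- uni$panel1$gene[grepl("biallelic", uni$panel1$expected_inheritance)]
  p1_mono <- uni$panel1$gene[grepl("monoallelic", uni$panel1$expected_inheritance)]

  state <- new.env()
  state$ann <- list(); state$calls <- list(); state$manifest <- list()
  state$decoys <- list(); state$counter <- 0L

  new_variant <- function(gene, af, consequence = "missense", qual = NULL,
                          depth = NULL, cadd = NULL, polyphen = TRUE, sift = TRUE,
                          acmg = "LP", splice_pred = FALSE, offset = 0L) {
    state$counter <- state$counter + 1L
    i <- state$counter
    ref_alt <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))[[i %% 4L + 1L]]
    chrom <- paste0("chr", (i %% 22L) + 1L)
    pos <- 10000L + i * 10L
    ac <- if (is.na(af)) NA_real_ else round(af * cfg$an_population)
    af_eff <- if (is.na(af)) NA_real_ else ac / cfg$an_population
    state$ann[[i]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref_alt[1], alt = ref_alt[2],
      gene = gene, transcript = paste0("NM_", 100000L + i),
      hgvs_c = paste0("c.", i, ref_alt[1], ">", ref_alt[2]),
      hgvs_p = paste0("p.V", i %% 997L + 1L, "M"),
      consequence = consequence, intron_offset = offset,
      gnomad_af = af_eff, gnomad_ac = ac,
      gnomad_an = if (is.na(af)) NA_real_ else cfg$an_population,
      cadd = if (is.null(cadd)) round(stats::runif(1, 16, 45), 2) else cadd,
      polyphen_damaging = polyphen, sift_deleterious = sift,
      acmg_class = acmg, splice_loss_predicted = splice_pred,
      established_pathogenic = FALSE,
      qual = if (is.null(qual)) round(stats::runif(1, 30, 99)) else qual,
      depth = if (is.null(depth)) sample(20:150, 1) else depth,
      stringsAsFactors = FALSE)
    i
  }
  add_call <- function(vi, samples, genotype) {
    a <- state$ann[[vi]]
    state$calls[[length(state$calls) + 1L]] <- data.frame(
      chrom = a$chrom, pos = a$pos, ref = a$ref, alt = a$alt,
      key = variant_key(a$chrom, a$pos, a$ref, a$alt),
      sample_id = samples, genotype = genotype, qual = a$qual, depth = a$depth,
      stringsAsFactors = FALSE)
  }
  vkey <- function(vi) {
    a <- state$ann[[vi]]
    variant_key(a$chrom, a$pos, a$ref, a$alt)
  }

  rare_af <- function(context) {
    fc <- filter_config()
    upper <- if (context == "biallelic") fc$maf_biallelic else fc$maf_monoallelic
    # mostly novel or near-novel, always strictly under the threshold
    stats::runif(1, 0, upper * 0.5)
  }

  plant_entity <- function(entity_id, entity_type, members, plan) {
    genes <- character(); keys <- character(); zygs <- character(); cats <- integer()
    plant1 <- function(gene, genotype, context, category, consequence = "missense",
                       acmg = "LP") {
      vi <- new_variant(gene, rare_af(context), consequence = consequence, acmg = acmg)
      add_call(vi, members, genotype)
      genes <<- c(genes, gene); keys <<- c(keys, vkey(vi))
      zygs <<- c(zygs, if (genotype == "hom_alt") "homozygous" else "heterozygous")
      cats <<- c(cats, category)
    }
    label <- NA_character_
    if (plan == "cat1_AR") {
      plant1(sample(p1_bi, 1), "hom_alt", "biallelic", 1L); label <- "AR"
    } else if (plan == "cat1_AD") {
      plant1(sample(p1_mono, 1), "het", "monoallelic", 1L); label <- "AD"
    } else if (plan == "cat1_CH") {
      g <- sample(p1_bi, 1)
      for (j in 1:2) {
        vi <- new_variant(g, rare_af("biallelic"))
        add_call(vi, members, "het")
        keys <- c(keys, vkey(vi))
      }
      genes <- c(genes, g); zygs <- c(zygs, "probable_compound_het")
      cats <- c(cats, 1L); label <- "CH"
    } else if (plan == "cat2_AD") {
      plant1(sample(uni$panel2$gene, 1), "het", "monoallelic", 2L); label <- "AD"
    } else if (plan == "cat2_CH") {
      g <- sample(uni$panel2$gene, 1)
      for (j in 1:2) {
        vi <- new_variant(g, rare_af("biallelic"))
        add_call(vi, members, "het")
        keys <- c(keys, vkey(vi))
      }
      genes <- c(genes, g); zygs <- c(zygs, "probable_compound_het")
      cats <- c(cats, 2L); label <- "CH"
    } else if (plan == "oligogenic") {
      plant1(sample(p1_mono, 1), "het", "monoallelic", 1L)
      plant1(sample(uni$panel2$gene, 1), "het", "monoallelic", 2L)
      label <- "oligogenic"
    } else if (plan == "cat3_hom") {
      plant1(sample(uni$candidates, 1), "hom_alt", "biallelic", 3L,
             consequence = "stop_gain", acmg = "P")
    } else if (plan == "other_phenotype_hom") {
      plant1(sample(uni$other_phenotype, 1), "hom_alt", "biallelic", 3L,
             consequence = "stop_gain", acmg = "P")
    }
    state$manifest[[length(state$manifest) + 1L]] <- data.frame(
      entity_id = entity_id, entity_type = entity_type, plan = plan,
      genes = paste(genes, collapse = ","),
      variant_keys = paste(sort(keys), collapse = ","),
      zygosity = paste(zygs, collapse = ","),
      categories = paste(cats, collapse = ","),
      expected_label = label, stringsAsFactors = FALSE)
  }

  for (i in seq_along(spo_ids)) {
    plant_entity(spo_ids[i], "sporadic_individual", spo_ids[i], spo_plan[i])
  }
  for (i in seq_along(kin_ids)) {
    plant_entity(kin_ids[i], "familial_kindred", fam_members[[i]], fam_plan[i])
  }

  # decoys: per affected individual, each violating exactly one stage -----
  affected <- pedigree$sample_id
  decoy_pool <- uni$decoy
  for (sid in affected) {
    for (stage in names(cfg$decoys_per_individual)) {
      n_d <- cfg$decoys_per_individual[[stage]]
      if (n_d == 0) next
      for (j in seq_len(n_d)) {
        g <- sample(decoy_pool, 1)
        vi <- switch(stage,
          quality = new_variant(g, rare_af("monoallelic"), qual = 10),
          insilico = new_variant(g, rare_af("monoallelic"), cadd = 6,
                                 polyphen = FALSE, sift = FALSE),
          rarity = new_variant(g, 0.05),
          synonymous_splice = new_variant(g, rare_af("monoallelic"),
                                          consequence = "synonymous"),
          acmg = new_variant(g, rare_af("monoallelic"), acmg = "VUS"))
        add_call(vi, sid, "het")
        state$decoys[[length(state$decoys) + 1L]] <- data.frame(
          sample_id = sid, stage = stage, variant_key = vkey(vi),
          stringsAsFactors = FALSE)
      }
    }
  }

  if (length(state$ann)) {
    ann <- do.call(rbind, state$ann)
    ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
    annotations <- validate_annotations(ann[, setdiff(names(ann), c("qual", "depth"))])
    calls <- do.call(rbind, state$calls)
    rownames(calls) <- NULL
  } else {
    annotations <- data.frame(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      gene = character(), transcript = character(), hgvs_c = character(),
      hgvs_p = character(), consequence = character(), intron_offset = integer(),
      gnomad_af = numeric(), gnomad_ac = numeric(), gnomad_an = numeric(),
      cadd = numeric(), polyphen_damaging = logical(), sift_deleterious = logical(),
      acmg_class = character(), splice_loss_predicted = logical(),
      established_pathogenic = logical(), key = character(),
      stringsAsFactors = FALSE)
    calls <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), key = character(), sample_id = character(),
                        genotype = character(), qual = numeric(), depth = numeric(),
                        stringsAsFactors = FALSE)
  }
  other <- data.frame(gene = uni$other_phenotype,
                      phenotype = "synthetic non-ovarian phenotype",
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, annotations = annotations, pedigree = pedigree,
                 panel1 = uni$panel1, panel2 = uni$panel2,
                 other_phenotype_genes = other,
                 manifest = do.call(rbind, state$manifest),
                 decoys = if (length(state$decoys)) do.call(rbind, state$decoys)
                          else data.frame(sample_id = character(), stage = character(),
                                          variant_key = character()),
                 config = cfg),
            class = "poi_cohort_bundle")
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits exactly the formats the readers consume: `cohort.vcf`,
#' `annotations.tsv`, `pedigree.ped`, `panel1.tsv`, `panel2.tsv`,
#' `other_phenotype_genes.tsv`, `truth_manifest.tsv`, `decoys.tsv`.
#'
#' @param bundle A `"poi_cohort_bundle"` from [generate_cohort()].
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    file.path(dir, f)
  }
  paths <- c(
    write_vcf(bundle$calls, file.path(dir, "cohort.vcf")),
    w(bundle$annotations[, setdiff(names(bundle$annotations), "key")],
      "annotations.tsv"),
    {
      ped <- bundle$pedigree
      ped_out <- data.frame(kindred_id = ped$kindred_id, sample_id = ped$sample_id,
                            father_id = ped$father_id, mother_id = ped$mother_id,
                            sex = ped$sex, affected = ifelse(ped$affected, 2, 1),
                            subcohort = ped$subcohort,
                            consanguineous = as.integer(ped$consanguineous))
      w(ped_out, "pedigree.ped")
    },
    w(bundle$panel1, "panel1.tsv"),
    w(bundle$panel2, "panel2.tsv"),
    w(bundle$other_phenotype_genes, "other_phenotype_genes.tsv"),
    w(bundle$manifest, "truth_manifest.tsv"),
    w(bundle$decoys, "decoys.tsv"))
  invisible(paths)
}

#' Perturb every planted variant to violate one named cascade stage
#'
#' Test harness: given a bundle, rewrites the annotations/calls of every
#' manifest variant so that it fails exactly the named stage; the pipeline
#' must then reject all of them there.
#'
#' @param bundle A `"poi_cohort_bundle"`.
#' @param stage One of `quality, insilico, rarity, synonymous_splice, acmg`.
#' @return The perturbed bundle.
#' @export
ablate <- function(bundle, stage) {
  stages <- c("quality", "insilico", "rarity", "synonymous_splice", "acmg")
  if (!stage %in% stages) stop("unknown stage: ", stage)
  keys <- unlist(strsplit(bundle$manifest$variant_keys, ",", fixed = TRUE))
  keys <- keys[keys != ""]
  ai <- bundle$annotations$key %in% keys
  ci <- bundle$calls$key %in% keys
  if (stage == "quality") {
    bundle$calls$qual[ci] <- 5
  } else if (stage == "insilico") {
    bundle$annotations$cadd[ai] <- 5
    bundle$annotations$polyphen_damaging[ai] <- FALSE
    bundle$annotations$sift_deleterious[ai] <- FALSE
    bundle$annotations$established_pathogenic[ai] <- FALSE
  } else if (stage == "rarity") {
    an <- bundle$annotations$gnomad_an[ai]
    an[is.na(an)] <- bundle$config$an_population
    bundle$annotations$gnomad_an[ai] <- an
    bundle$annotations$gnomad_ac[ai] <- round(0.05 * an)
    bundle$annotations$gnomad_af[ai] <- round(0.05 * an) / an
    bundle$annotations$established_pathogenic[ai] <- FALSE
  } else if (stage == "synonymous_splice") {
    bundle$annotations$consequence[ai] <- "synonymous"
    bundle$annotations$intron_offset[ai] <- 0L
    bundle$annotations$splice_loss_predicted[ai] <- FALSE
    bundle$annotations$established_pathogenic[ai] <- FALSE
  } else if (stage == "acmg") {
    bundle$annotations$acmg_class[ai] <- "VUS"
    bundle$annotations$established_pathogenic[ai] <- FALSE
  }
  bundle
}

#' @export
print.poi_cohort_bundle <- function(x, ...) {
  cat("Synthetic POI cohort bundle\n")
  cat(sprintf("  %d individuals (%d sporadic, %d familial kindreds), seed %d\n",
              nrow(x$pedigree), x$config$n_sporadic, x$config$n_familial_kindreds,
              x$config$seed))
  cat(sprintf("  %d variant annotations, %d calls, %d decoys\n",
              nrow(x$annotations), nrow(x$calls), nrow(x$decoys)))
  invisible(x)
}
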