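# A small cohort keeps the recovery tests fast while exercising every
# plant type and decoy stage.
small_cfg <- function(seed = 1, decoys = c(quality = 1, insilico = 1, rarity = 1,
                                           synonymous_splice = 1, acmg = 1)) {
  simulation_config(n_sporadic = 30, n_familial_kindreds = 6, seed = seed,
                    decoys_per_individual = decoys)
}

no_decoys <- c(quality = 0, insilico = 0, rarity = 0, synonymous_splice = 0,
               acmg = 0)

test_that("identical seed and config give identical bundles and files", {
  b1 <- generate_cohort(small_cfg(seed = 42))
  b2 <- generate_cohort(small_cfg(seed = 42))
  expect_identical(b1$calls, b2$calls)
  expect_identical(b1$annotations, b2$annotations)
  expect_identical(b1$manifest, b2$manifest)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort_bundle(b1, d1); write_cohort_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  b3 <- generate_cohort(small_cfg(seed = 43))
  expect_false(identical(b1$calls, b3$calls))
})

test_that("with zero decoys the pipeline recovers the truth manifest exactly", {
  bundle <- generate_cohort(small_cfg(seed = 7, decoys = no_decoys))
  scr <- screen_bundle(bundle)
  man <- bundle$manifest

  # findings must equal the manifest as a set over (entity, gene, category)
  planted <- man[man$plan != "no_finding", ]
  got <- character()
  for (i in seq_len(nrow(planted))) {
    ent <- planted$entity_id[i]
    genes <- strsplit(planted$genes[i], ",")[[1]]
    cats <- as.integer(strsplit(planted$categories[i], ",")[[1]])
    zygs <- strsplit(planted$zygosity[i], ",")[[1]]
    if (planted$entity_type[i] == "sporadic_individual") {
      fi <- scr$findings[scr$findings$sample_id == ent, ]
    } else {
      fi <- scr$kindred_findings[scr$kindred_findings$kindred_id == ent, ]
    }
    expect_equal(nrow(fi), length(genes), info = ent)
    expect_setequal(fi$gene, genes)
    expect_equal(fi$category[match(genes, fi$gene)], cats)
    expect_equal(fi$zygosity[match(genes, fi$gene)], zygs)
  }
  # no extra findings beyond the manifest
  expect_equal(nrow(scr$findings),
               sum(lengths(strsplit(planted$genes[planted$entity_type ==
                                                    "sporadic_individual"], ","))) +
                 sum(vapply(which(planted$entity_type == "familial_kindred"),
                            function(i) {
                              length(strsplit(planted$genes[i], ",")[[1]]) *
                                bundle$config$kindred_size
                            }, numeric(1))))

  # expected labels recovered at the right level
  exp_lab <- planted[!is.na(planted$expected_label), ]
  for (i in seq_len(nrow(exp_lab))) {
    ent <- exp_lab$entity_id[i]
    if (exp_lab$entity_type[i] == "sporadic_individual") {
      expect_equal(scr$labels$label[scr$labels$sample_id == ent],
                   exp_lab$expected_label[i], info = ent)
    } else {
      expect_equal(scr$kindred_labels$label[scr$kindred_labels$kindred_id == ent],
                   exp_lab$expected_label[i], info = ent)
    }
  }
})

test_that("every decoy is rejected at the stage it was built to violate", {
  bundle <- generate_cohort(small_cfg(seed = 19))
  scr <- screen_bundle(bundle)
  cfg <- filter_config()
  jn <- join_annotations(bundle$calls, bundle$annotations)$annotated
  for (i in seq_len(nrow(bundle$decoys))) {
    d <- bundle$decoys[i, ]
    row <- jn[jn$key == d$variant_key & jn$sample_id == d$sample_id, ]
    v <- run_filter_cascade(row, "monoallelic", cfg)
    expect_false(v$passed)
    expect_equal(v$failed_stages, d$stage, info = d$variant_key)
  }
  # no decoy gene ever reaches the findings, and no planted variant is lost
  expect_false(any(grepl("^DECOY", scr$findings$gene)))
  planted_keys <- unlist(strsplit(bundle$manifest$variant_keys, ","))
  planted_keys <- planted_keys[planted_keys != ""]
  found_keys <- unlist(strsplit(scr$findings$variant_keys, ","))
  expect_true(all(planted_keys %in% found_keys))
  # the run log attributes the right number of rarity rejections
  n_rarity_decoy_calls <- sum(bundle$calls$key %in%
                                bundle$decoys$variant_key[bundle$decoys$stage == "rarity"])
  expect_equal(scr$log$stage_rejections$rarity, n_rarity_decoy_calls)
})

test_that("ablation makes the pipeline reject every planted variant at that stage", {
  base <- generate_cohort(small_cfg(seed = 5, decoys = no_decoys))
  for (stage in c("quality", "insilico", "rarity", "synonymous_splice", "acmg")) {
    scr <- screen_bundle(ablate(base, stage))
    expect_equal(nrow(scr$findings), 0L, info = stage)
    expect_gt(scr$log$stage_rejections[[stage]], 0)
  }
  expect_error(ablate(base, "nonsense"), "unknown stage")
})

test_that("degenerate compositions behave as specified", {
  comp0 <- c(cat1_AR = 0, cat1_AD = 0, cat1_CH = 0, cat2_AD = 0, cat2_CH = 0,
             oligogenic = 0, cat3_hom = 0, other_phenotype_hom = 0, no_finding = 1)
  bundle <- generate_cohort(simulation_config(n_sporadic = 8, n_familial_kindreds = 2,
                                              composition_sporadic = comp0,
                                              composition_familial = comp0,
                                              decoys_per_individual = no_decoys,
                                              seed = 3))
  scr <- screen_bundle(bundle)
  expect_equal(nrow(scr$findings), 0L)

  comp1 <- c(cat1_AR = 1, cat1_AD = 0, cat1_CH = 0, cat2_AD = 0, cat2_CH = 0,
             oligogenic = 0, cat3_hom = 0, other_phenotype_hom = 0, no_finding = 0)
  bundle1 <- generate_cohort(simulation_config(n_sporadic = 1, n_familial_kindreds = 2,
                                               composition_sporadic = comp1,
                                               composition_familial = comp0,
                                               decoys_per_individual = no_decoys,
                                               seed = 3))
  scr1 <- screen_bundle(bundle1)
  expect_equal(nrow(scr1$findings), 1L)
  expect_equal(scr1$findings$category, 1L)
  expect_equal(scr1$labels$label, "AR")
})
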