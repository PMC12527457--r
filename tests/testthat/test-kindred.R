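tp <- toy_panels()

make_ped <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], kindred_id = r[[2]], father_id = "0",
               mother_id = "0", sex = "2", affected = r[[3]],
               subcohort = r[[4]], consanguineous = FALSE,
               stringsAsFactors = FALSE)
  }))
}

finding_row <- function(sid, kid, gene, keys, zyg, cat, tier = "green") {
  data.frame(sample_id = sid, kindred_id = kid, gene = gene,
             variant_keys = keys, n_variants = length(strsplit(keys, ",")[[1]]),
             zygosity = zyg, category = cat, tier = tier,
             reroute_reason = "none", other_phenotype_flag = FALSE,
             stringsAsFactors = FALSE)
}

test_that("kindred aggregation intersects variant sets across affected members", {
  ped <- make_ped(list("A1", "K1", TRUE, "familial"),
                  list("A2", "K1", TRUE, "familial"))
  f <- rbind(finding_row("A1", "K1", "STAG3", "chr1:1:A:T", "homozygous", 1L),
             finding_row("A2", "K1", "STAG3", "chr1:1:A:T", "homozygous", 1L))
  kin <- aggregate_kindred(f, calls = f[0, ], pedigree = ped,
                           panel1 = tp$panel1, panel2 = tp$panel2)
  expect_equal(nrow(kin$findings), 1L)
  expect_equal(kin$findings$zygosity, "homozygous")
  expect_equal(kin$findings$category, 1L)
  expect_equal(kin$findings$segregation_status, "untestable")
  expect_equal(kin$labels$label, "AR")

  # sibs sharing no variant: no kindred finding
  f2 <- rbind(finding_row("A1", "K1", "STAG3", "chr1:1:A:T", "homozygous", 1L),
              finding_row("A2", "K1", "STAG3", "chr1:9:G:C", "homozygous", 1L))
  kin2 <- aggregate_kindred(f2, calls = f2[0, ], pedigree = ped,
                            panel1 = tp$panel1, panel2 = tp$panel2)
  expect_equal(nrow(kin2$findings), 0L)
  # a gene found in only one of two affected members is not kindred-level
  f3 <- finding_row("A1", "K1", "STAG3", "chr1:1:A:T", "homozygous", 1L)
  kin3 <- aggregate_kindred(f3, calls = f3[0, ], pedigree = ped,
                            panel1 = tp$panel1, panel2 = tp$panel2)
  expect_equal(nrow(kin3$findings), 0L)
})

test_that("kindred findings never contain a variant absent from every member", {
  scr <- screen_familial()
  member_keys <- unlist(strsplit(scr$findings$variant_keys, ",", fixed = TRUE))
  kindred_keys <- unlist(strsplit(scr$kindred_findings$shared_variant_keys, ",",
                                  fixed = TRUE))
  expect_true(all(kindred_keys %in% member_keys))
})

test_that("discordant member zygosity flags the kindred finding", {
  ped <- make_ped(list("A1", "K1", TRUE, "familial"),
                  list("A2", "K1", TRUE, "familial"))
  f <- rbind(finding_row("A1", "K1", "STAG3", "chr1:1:A:T", "homozygous", 1L),
             finding_row("A2", "K1", "STAG3", "chr1:1:A:T,chr1:9:G:C",
                         "probable_compound_het", 1L))
  kin <- aggregate_kindred(f, calls = f[0, ], pedigree = ped,
                           panel1 = tp$panel1, panel2 = tp$panel2)
  expect_equal(kin$findings$segregation_status, "inconsistent")
})

test_that("segregation checks use unaffected relatives when genotyped", {
  un_calls <- function(sid, key, gt) {
    data.frame(sample_id = sid, key = key, genotype = gt, stringsAsFactors = FALSE)
  }
  # unaffected carrier parent is consistent with AR
  expect_equal(check_segregation("homozygous", "k1", un_calls("M", "k1", "het")),
               "consistent")
  # unaffected homozygote breaks AR
  expect_equal(check_segregation("homozygous", "k1", un_calls("M", "k1", "hom_alt")),
               "inconsistent")
  # unaffected carrier breaks AD under the full-penetrance assumption
  expect_equal(check_segregation("heterozygous", "k1", un_calls("M", "k1", "het")),
               "inconsistent")
  # unaffected relative carrying both CH alleles breaks CH
  both <- rbind(un_calls("M", "k1", "het"), un_calls("M", "k2", "het"))
  expect_equal(check_segregation("probable_compound_het", c("k1", "k2"), both),
               "inconsistent")
  expect_equal(check_segregation("probable_compound_het", c("k1", "k2"),
                                 un_calls("M", "k1", "het")),
               "consistent")
  # nobody genotyped -> untestable
  expect_equal(check_segregation("homozygous", "k1", NULL), "untestable")
})

test_that("a proven-cis het pair collapses to its rarer member", {
  ped <- data.frame(sample_id = c("P", "DAD", "MUM"), kindred_id = "K1",
                    father_id = c("DAD", "0", "0"), mother_id = c("MUM", "0", "0"),
                    sex = c("2", "1", "2"), affected = c(TRUE, FALSE, FALSE),
                    subcohort = c("familial", "relative", "relative"),
                    consanguineous = FALSE, stringsAsFactors = FALSE)
  ann <- data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "T",
    gene = "STAG3", transcript = "NM_1", hgvs_c = c("c.1A>T", "c.2A>T"),
    hgvs_p = "", consequence = "missense", intron_offset = 0L,
    gnomad_af = c(4e-5, 1e-5), gnomad_ac = c(65, 16), gnomad_an = 1614000,
    cadd = 25, polyphen_damaging = TRUE, sift_deleterious = TRUE,
    acmg_class = "LP", splice_loss_predicted = FALSE,
    established_pathogenic = FALSE, stringsAsFactors = FALSE)
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  call_row <- function(sid, i, gt) {
    data.frame(chrom = "chr1", pos = ann$pos[i], ref = "A", alt = "T",
               key = ann$key[i], sample_id = sid, genotype = gt, qual = 99,
               depth = 75, stringsAsFactors = FALSE)
  }
  # both variants on the paternal haplotype: dad carries both, but with mum
  # ungenotyped the phase stays unproven and the pair remains probable CH
  calls <- rbind(call_row("P", 1, "het"), call_row("P", 2, "het"),
                 call_row("DAD", 1, "het"), call_row("DAD", 2, "het"))
  scr <- poi_screen(calls, ann, ped, tp$panel1, tp$panel2)
  expect_equal(scr$findings$zygosity, "probable_compound_het")
  expect_equal(scr$findings$category, 1L)
  # once mum is genotyped as a non-carrier the pair is proven cis
  calls2 <- rbind(calls, call_row("MUM", 1, "hom_ref"))
  scr2 <- poi_screen(calls2, ann, ped, tp$panel1, tp$panel2)
  expect_equal(scr2$findings$zygosity, "heterozygous")
  expect_equal(scr2$findings$variant_keys, ann$key[2])  # rarer member kept
  # rerouted: a lone het in a biallelic-expected panel-1 gene is Category 2
  expect_equal(scr2$findings$category, 2L)
})
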