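# Shared, lazily-computed fixtures: the published-table bundles and their
# screens are expensive enough to build once per test run.
.tierpoi_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .tierpoi_cache)) {
    assign(name, force(expr), envir = .tierpoi_cache)
  }
  get(name, envir = .tierpoi_cache)
}

table_fixtures <- function() cached("fx", make_table_fixtures())

screen_familial <- function() cached("scr_f", {
  fx <- table_fixtures()
  poi_screen(fx$familial$calls, fx$familial$annotations, fx$familial$pedigree,
             fx$panel1, fx$panel2,
             other_phenotype_genes = fx$other_phenotype_genes$gene)
})

screen_sporadic <- function() cached("scr_s", {
  fx <- table_fixtures()
  poi_screen(fx$sporadic$calls, fx$sporadic$annotations, fx$sporadic$pedigree,
             fx$panel1, fx$panel2,
             other_phenotype_genes = fx$other_phenotype_genes$gene)
})

screen_combined <- function() cached("scr_c", {
  fx <- table_fixtures()
  poi_screen(fx$combined$calls, fx$combined$annotations, fx$combined$pedigree,
             fx$panel1, fx$panel2,
             other_phenotype_genes = fx$other_phenotype_genes$gene)
})

# A minimal annotated-call row with every field the cascade consumes;
# override any field by name.
ann_call <- function(...) {
  base <- list(qual = 99, depth = 75, cadd = 25, polyphen_damaging = TRUE,
               sift_deleterious = TRUE, gnomad_af = 0, consequence = "missense",
               intron_offset = 0L, splice_loss_predicted = FALSE,
               acmg_class = "LP", established_pathogenic = FALSE)
  utils::modifyList(base, list(...))
}

# Tiny two-gene panels for unit tests of the classifier.
toy_panels <- function() {
  p1 <- data.frame(gene = c("STAG3", "POLR2C"), category = 1L,
                   tier = c("green", "amber"),
                   expected_inheritance = c("biallelic", "monoallelic"),
                   source_note = "", stringsAsFactors = FALSE)
  p2 <- data.frame(gene = c("NLRP11", "PLEC"), category = 2L, tier = "none",
                   expected_inheritance = "biallelic|monoallelic",
                   source_note = "", stringsAsFactors = FALSE)
  list(panel1 = p1, panel2 = p2)
}
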