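cfg <- filter_config()

test_that("quality thresholds are inclusive at the stated boundaries", {
  expect_true(passes_quality(20, 10, cfg))
  expect_false(passes_quality(19, 100, cfg))
  expect_false(passes_quality(75, 9, cfg))
  expect_false(passes_quality(NA, 50, cfg))
  expect_false(passes_quality(50, NA, cfg))
})

test_that("in-silico rule needs 2 of 3 votes with a strict CADD cutoff", {
  expect_true(insilico_deleterious(16, FALSE, TRUE, FALSE, cfg))     # 2 votes
  expect_false(insilico_deleterious(15, NA, TRUE, FALSE, cfg))       # 15 is not > 15
  expect_true(insilico_deleterious(15.01, NA, TRUE, FALSE, cfg))
  expect_false(insilico_deleterious(NA, NA, TRUE, FALSE, cfg))       # missing = non-vote
  expect_true(insilico_deleterious(8, FALSE, FALSE, TRUE, cfg))      # allowlist bypass
})

test_that("rarity is strict and zygosity-context dependent; novel passes", {
  expect_true(passes_rarity(6.195e-7, "biallelic", cfg))
  expect_true(passes_rarity(0, "monoallelic", cfg))
  expect_true(passes_rarity(NA, "monoallelic", cfg))
  expect_false(passes_rarity(1e-4, "biallelic", cfg))    # strict boundary
  expect_false(passes_rarity(5e-5, "monoallelic", cfg))  # strict boundary
  expect_true(passes_rarity(9.9e-5, "biallelic", cfg))
  expect_false(passes_rarity(9.9e-5, "monoallelic", cfg))
})

test_that("synonymous/splice retention follows the 7-base window or a prediction", {
  expect_true(synonymous_retention("missense", 0L, FALSE, cfg))
  expect_false(synonymous_retention("synonymous", 0L, FALSE, cfg))
  expect_true(synonymous_retention("synonymous", 0L, TRUE, cfg))
  expect_true(synonymous_retention("splice_site", 2L, TRUE, cfg))
  expect_true(synonymous_retention("splice_site", -7L, FALSE, cfg))   # window edge
  expect_false(synonymous_retention("intronic", 8L, FALSE, cfg))
  expect_true(synonymous_retention("intronic", -1652L, TRUE, cfg))    # deep + predicted
  expect_false(synonymous_retention("intronic", 589L, NA, cfg))
})

test_that("only P/LP ACMG classes are retained", {
  expect_true(acmg_retained("LP"))
  expect_true(acmg_retained("P"))
  expect_false(acmg_retained("VUS"))
  expect_false(acmg_retained(NA))
})

test_that("cascade reports every failed stage and honors the bypass", {
  v <- run_filter_cascade(ann_call(gnomad_af = 0.002), "monoallelic", cfg)
  expect_false(v$passed)
  expect_equal(v$failed_stages, "rarity")

  v <- run_filter_cascade(ann_call(), "biallelic", cfg)
  expect_true(v$passed)
  expect_length(v$failed_stages, 0)

  # homozygous stop-gain, af 0, P: the printed-type fully-passing call
  v <- run_filter_cascade(ann_call(consequence = "stop_gain", acmg_class = "P"),
                          "biallelic", cfg)
  expect_true(v$passed)

  # synonymous exonic with high CADD still fails the synonymous stage
  v <- run_filter_cascade(ann_call(consequence = "synonymous", cadd = 30),
                          "monoallelic", cfg)
  expect_equal(v$failed_stages, "synonymous_splice")

  # several violations are all reported, in cascade order
  v <- run_filter_cascade(ann_call(qual = 5, gnomad_af = 0.002, acmg_class = "VUS"),
                          "monoallelic", cfg)
  expect_equal(v$failed_stages, c("quality", "rarity", "acmg"))

  # established-POI bypass skips every retention stage but never quality
  v <- run_filter_cascade(ann_call(cadd = 2, polyphen_damaging = FALSE,
                                   sift_deleterious = FALSE, gnomad_af = 0.005,
                                   acmg_class = "B", established_pathogenic = TRUE),
                          "monoallelic", cfg)
  expect_true(v$passed)
  expect_true(v$bypass_used)
  v <- run_filter_cascade(ann_call(qual = 10, established_pathogenic = TRUE),
                          "monoallelic", cfg)
  expect_false(v$passed)
  expect_equal(v$failed_stages, "quality")
})

test_that("cascade verdict is independent of stage evaluation order", {
  set.seed(42)
  for (i in 1:50) {
    call <- ann_call(
      qual = sample(c(5, 20, 99), 1), depth = sample(c(5, 10, 80), 1),
      cadd = sample(c(NA, 5, 16), 1),
      polyphen_damaging = sample(c(NA, TRUE, FALSE), 1),
      sift_deleterious = sample(c(NA, TRUE, FALSE), 1),
      gnomad_af = sample(c(0, 4e-5, 9e-5, 2e-4), 1),
      consequence = sample(c("missense", "synonymous", "intronic"), 1),
      splice_loss_predicted = sample(c(NA, TRUE, FALSE), 1),
      acmg_class = sample(c("P", "LP", "VUS", NA), 1))
    call$intron_offset <- if (call$consequence == "intronic") sample(c(2L, 30L), 1) else 0L
    ctx <- sample(c("biallelic", "monoallelic"), 1)
    v <- run_filter_cascade(call, ctx, cfg)
    # independent recomputation as an unordered conjunction of predicates
    bypass <- isTRUE(call$established_pathogenic)
    stages_ok <- c(
      passes_quality(call$qual, call$depth, cfg),
      bypass || insilico_deleterious(call$cadd, call$polyphen_damaging,
                                     call$sift_deleterious, FALSE, cfg),
      bypass || passes_rarity(call$gnomad_af, ctx, cfg),
      bypass || synonymous_retention(call$consequence, call$intron_offset,
                                     call$splice_loss_predicted, cfg),
      bypass || acmg_retained(call$acmg_class))
    expect_equal(v$passed, all(stages_ok))
  }
})

test_that("tightening any threshold never grows the retained set", {
  set.seed(7)
  n <- 300
  pool <- data.frame(
    qual = round(stats::runif(n, 0, 99)),
    depth = sample(1:120, n, replace = TRUE),
    cadd = ifelse(stats::runif(n) < .1, NA, stats::runif(n, 0, 45)),
    polyphen_damaging = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    sift_deleterious = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    gnomad_af = stats::runif(n, 0, 3e-4),
    consequence = sample(c("missense", "synonymous", "intronic", "stop_gain"),
                         n, replace = TRUE),
    splice_loss_predicted = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    acmg_class = sample(c("P", "LP", "VUS", "B"), n, replace = TRUE),
    established_pathogenic = FALSE)
  pool$intron_offset <- ifelse(pool$consequence == "intronic",
                               sample(c(-30L, -5L, 3L, 10L), n, replace = TRUE), 0L)
  ctx <- sample(c("biallelic", "monoallelic"), n, replace = TRUE)

  retained <- function(cfg) {
    sum(vapply(seq_len(n), function(i) {
      run_filter_cascade(pool[i, ], ctx[i], cfg)$passed
    }, logical(1)))
  }
  base <- retained(filter_config())
  tighter <- list(
    filter_config(min_qual = 30),
    filter_config(min_depth = 20),
    filter_config(cadd_cutoff = 25),
    filter_config(insilico_votes_required = 3),
    filter_config(maf_biallelic = 5e-5, maf_monoallelic = 2e-5),
    filter_config(intronic_splice_window = 3))
  for (cfg_t in tighter) expect_lte(retained(cfg_t), base)
})
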