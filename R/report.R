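#' Round half-up to a fixed number of decimals
#'
#' Presentation rounding for percentages (exactly .05 rounds up, matching
#' the reporting style of clinical tables rather than banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

.pct <- function(n, d) round_half_up(100 * n / d, 1)

.label_counts <- function(labels) {
  out <- c(AD = 0L, AR = 0L, CH = 0L, oligogenic = 0L)
  t <- table(factor(labels, levels = names(out)))
  out[names(t)] <- as.integer(t)
  out
}

#' Cohort-level summary of a tiered screen
#'
#' Computes every cohort-level detection statistic: per-category counts and
#' proportions and inheritance-mode counts at three levels -- sporadic
#' (individuals), familial (kindreds), and merged "entities" (each sporadic
#' individual and each familial kindred counting once) -- plus distinct
#' Category 1/2 gene and variant tallies, Category 3 candidate carriers
#' (other-phenotype-flagged genes excluded), and familial-vs-sporadic mode
#' contrasts by two-tailed Fisher exact test. Proportions are kept at full
#' precision and rounded half-up to 1 decimal only in the `*_pct` fields.
#'
#' @param findings,labels,kindred_findings,kindred_labels Components of a
#'   [poi_screen()] result.
#' @param pedigree Pedigree data.frame.
#' @param cfg A [filter_config()] (summary alpha).
#' @return A list of class `"poi_summary"`.
#' @export
summarize_cohort <- function(findings, labels, kindred_findings, kindred_labels,
                             pedigree, cfg = filter_config()) {
  aff <- pedigree[pedigree$affected, , drop = FALSE]
  if (!nrow(aff)) stop("empty cohort: no affected individuals in pedigree")
  spo_ids <- aff$sample_id[aff$subcohort == "sporadic"]
  fam_kids <- unique(aff$kindred_id[aff$subcohort == "familial"])

  use <- findings[!findings$other_phenotype_flag, , drop = FALSE]
  cat12_by_sample <- function(ids) {
    f <- use[use$sample_id %in% ids & use$category %in% c(1L, 2L), , drop = FALSE]
    list(with = unique(f$sample_id),
         cat1 = unique(f$sample_id[f$category == 1L]))
  }

  # --- sporadic, individual level -------------------------------------
  s <- cat12_by_sample(spo_ids)
  spo_cat2_only <- setdiff(s$with, s$cat1)
  spo_lab <- labels[labels$sample_id %in% spo_ids, , drop = FALSE]
  spo_cat3 <- unique(use$sample_id[use$sample_id %in% spo_ids & use$category == 3L])

  # --- familial, kindred level ----------------------------------------
  kuse <- kindred_findings[!kindred_findings$other_phenotype_flag &
                             kindred_findings$kindred_id %in% fam_kids, , drop = FALSE]
  fam_with <- unique(kuse$kindred_id[kuse$category %in% c(1L, 2L)])
  fam_cat1 <- unique(kuse$kindred_id[kuse$category == 1L])
  fam_cat2_only <- setdiff(fam_with, fam_cat1)
  fam_lab <- kindred_labels[kindred_labels$kindred_id %in% fam_kids, , drop = FALSE]
  fam_cat3 <- unique(kuse$kindred_id[kuse$category == 3L])

  # --- merged entities -------------------------------------------------
  ent_labels <- c(spo_lab$label, fam_lab$label)
  ent_counts <- .label_counts(ent_labels)
  n_entities <- length(spo_lab$label) + length(fam_lab$label)

  cat12 <- use[use$category %in% c(1L, 2L), , drop = FALSE]
  all_keys <- unique(unlist(strsplit(cat12$variant_keys, ",", fixed = TRUE)))
  fam_women_with <- unique(use$sample_id[use$sample_id %in%
                                           aff$sample_id[aff$subcohort == "familial"] &
                                           use$category %in% c(1L, 2L)])
  cat3_women <- unique(use$sample_id[use$category == 3L])

  out <- list(
    n = list(sporadic_individuals = length(spo_ids),
             familial_kindreds = length(fam_kids),
             familial_individuals = sum(aff$subcohort == "familial")),
    sporadic = list(
      n_with_cat12 = length(s$with),
      with_cat12_pct = .pct(length(s$with), length(spo_ids)),
      n_cat1 = length(s$cat1),
      cat1_pct = .pct(length(s$cat1), length(spo_ids)),
      n_cat2_only = length(spo_cat2_only),
      cat2_only_pct = .pct(length(spo_cat2_only), length(spo_ids)),
      labels = .label_counts(spo_lab$label),
      labels_pct = .pct(.label_counts(spo_lab$label), length(spo_ids)),
      n_cat3_women = length(spo_cat3)
    ),
    familial = list(
      n_with_cat12 = length(fam_with),
      with_cat12_pct = .pct(length(fam_with), length(fam_kids)),
      n_cat1 = length(fam_cat1),
      cat1_pct = .pct(length(fam_cat1), length(fam_kids)),
      n_cat2_only = length(fam_cat2_only),
      cat2_only_pct = .pct(length(fam_cat2_only), length(fam_kids)),
      labels = .label_counts(fam_lab$label),
      labels_pct = .pct(.label_counts(fam_lab$label), length(fam_kids)),
      n_cat3_kindreds = length(fam_cat3),
      n_women_with_cat12 = length(fam_women_with)
    ),
    entities = list(
      n_with_cat12 = n_entities,
      labels = ent_counts,
      labels_pct = .pct(ent_counts, n_entities)
    ),
    genes = list(distinct_gene_count = length(unique(cat12$gene)),
                 variant_count = length(all_keys)),
    category3 = list(n_women = length(cat3_women)),
    alpha = cfg$summary_alpha
  )
  out$comparisons <- if (length(spo_ids) && length(fam_kids)) {
    compare_subcohorts(out, cfg)
  } else {
    # single-subcohort cohorts have nothing to contrast
    data.frame(description = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), p = numeric(),
               significant = logical(), note = character(),
               stringsAsFactors = FALSE)
  }
  structure(out, class = "poi_summary")
}

#' Familial-vs-sporadic inheritance-mode contrasts
#'
#' Builds, at entity level, the 2x2 table (mode vs subcohort) for the
#' homozygous (AR) and single-heterozygous (AD) labels with the full
#' subcohort sizes as denominators, and tests each with the two-tailed
#' Fisher exact test against `cfg$summary_alpha`. Degenerate tables (an
#' empty margin) are skipped with a note.
#'
#' @param summary A `"poi_summary"` (or the list being built).
#' @param cfg A [filter_config()].
#' @return Data.frame: `description, a, b, c, d, p, significant, note`.
#' @export
compare_subcohorts <- function(summary, cfg = filter_config()) {
  n_fam <- summary$n$familial_kindreds
  n_spo <- summary$n$sporadic_individuals
  if (n_fam == 0L || n_spo == 0L) stop("both subcohorts must be non-empty")
  one <- function(desc, fam_n, spo_n) {
    a <- fam_n; b <- n_fam - fam_n; c <- spo_n; d <- n_spo - spo_n
    if ((a + c) == 0L || (b + d) == 0L) {
      return(data.frame(description = desc, a = a, b = b, c = c, d = d,
                        p = NA_real_, significant = NA,
                        note = "degenerate margins; comparison skipped",
                        stringsAsFactors = FALSE))
    }
    p <- fisher_exact_two_tailed(a, b, c, d)
    data.frame(description = desc, a = a, b = b, c = c, d = d, p = p,
               significant = p < cfg$summary_alpha, note = "",
               stringsAsFactors = FALSE)
  }
  rbind(
    one("homozygous (AR) label, familial kindreds vs sporadic individuals",
        summary$familial$labels[["AR"]], summary$sporadic$labels[["AR"]]),
    one("single heterozygous (AD) label, familial kindreds vs sporadic individuals",
        summary$familial$labels[["AD"]], summary$sporadic$labels[["AD"]])
  )
}

#' Summarize a tiered screen
#'
#' @param object A `"poi_screen"` object.
#' @param ... Unused.
#' @return A `"poi_summary"`; see [summarize_cohort()].
#' @export
summary.poi_screen <- function(object, ...) {
  summarize_cohort(object$findings, object$labels, object$kindred_findings,
                   object$kindred_labels, object$pedigree, object$config)
}

#' @export
print.poi_summary <- function(x, ...) {
  cat("Cohort summary (tiered POI screen)\n")
  cat(sprintf("  cohort: %d sporadic individuals; %d familial kindreds (%d women)\n",
              x$n$sporadic_individuals, x$n$familial_kindreds, x$n$familial_individuals))
  cat(sprintf("  sporadic: %d/%d (%.1f%%) with Category 1/2 finding; cat1 %d (%.1f%%), cat2-only %d (%.1f%%)\n",
              x$sporadic$n_with_cat12, x$n$sporadic_individuals, x$sporadic$with_cat12_pct,
              x$sporadic$n_cat1, x$sporadic$cat1_pct,
              x$sporadic$n_cat2_only, x$sporadic$cat2_only_pct))
  cat(sprintf("  familial: %d/%d (%.1f%%) kindreds with Category 1/2 finding; cat1 %d (%.1f%%), cat2-only %d (%.1f%%)\n",
              x$familial$n_with_cat12, x$n$familial_kindreds, x$familial$with_cat12_pct,
              x$familial$n_cat1, x$familial$cat1_pct,
              x$familial$n_cat2_only, x$familial$cat2_only_pct))
  lm <- x$entities$labels; lp <- x$entities$labels_pct
  cat(sprintf("  merged entities with findings: %d; modes: AD %d (%.1f%%), AR %d (%.1f%%), CH %d (%.1f%%), oligogenic %d (%.1f%%)\n",
              x$entities$n_with_cat12, lm[["AD"]], lp[["AD"]], lm[["AR"]], lp[["AR"]],
              lm[["CH"]], lp[["CH"]], lm[["oligogenic"]], lp[["oligogenic"]]))
  cat(sprintf("  Category 1/2: %d distinct genes, %d distinct variants\n",
              x$genes$distinct_gene_count, x$genes$variant_count))
  cat(sprintf("  Category 3 candidate carriers: %d women\n", x$category3$n_women))
  for (i in seq_len(nrow(x$comparisons))) {
    cm <- x$comparisons[i, ]
    cat(sprintf("  %s: [[%d,%d],[%d,%d]] p = %.4g%s\n", cm$description,
                cm$a, cm$b, cm$c, cm$d, cm$p,
                if (isTRUE(cm$significant)) " (significant)" else ""))
  }
  invisible(x)
}

#' Write the cohort summary report files
#'
#' Emits `summary.json` (machine-readable, round-trips through
#' [jsonlite::read_json()]), `summary_by_category.tsv`,
#' `summary_by_mode.tsv` and `comparisons.tsv`, with every percentage at
#' 1 decimal place. Empty mode cells are written as explicit zero rows.
#'
#' @param summary A `"poi_summary"`.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("summary.json", "summary_by_category.tsv",
                            "summary_by_mode.tsv", "comparisons.tsv"))
  json <- unclass(summary)
  json$sporadic$labels <- as.list(summary$sporadic$labels)
  json$sporadic$labels_pct <- as.list(summary$sporadic$labels_pct)
  json$familial$labels <- as.list(summary$familial$labels)
  json$familial$labels_pct <- as.list(summary$familial$labels_pct)
  json$entities$labels <- as.list(summary$entities$labels)
  json$entities$labels_pct <- as.list(summary$entities$labels_pct)
  jsonlite::write_json(json, paths[1], auto_unbox = TRUE, pretty = TRUE, digits = NA)

  by_cat <- data.frame(
    level = c("sporadic", "sporadic", "sporadic", "familial", "familial", "familial"),
    measure = rep(c("cat1_or_cat2", "cat1", "cat2_only"), 2),
    n = c(summary$sporadic$n_with_cat12, summary$sporadic$n_cat1,
          summary$sporadic$n_cat2_only, summary$familial$n_with_cat12,
          summary$familial$n_cat1, summary$familial$n_cat2_only),
    denominator = c(rep(summary$n$sporadic_individuals, 3),
                    rep(summary$n$familial_kindreds, 3)),
    pct = c(summary$sporadic$with_cat12_pct, summary$sporadic$cat1_pct,
            summary$sporadic$cat2_only_pct, summary$familial$with_cat12_pct,
            summary$familial$cat1_pct, summary$familial$cat2_only_pct),
    stringsAsFactors = FALSE)
  utils::write.table(by_cat, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)

  modes <- names(summary$entities$labels)
  by_mode <- data.frame(
    level = rep(c("sporadic", "familial", "entities"), each = length(modes)),
    mode = rep(modes, 3),
    n = c(summary$sporadic$labels, summary$familial$labels, summary$entities$labels),
    pct = c(summary$sporadic$labels_pct, summary$familial$labels_pct,
            summary$entities$labels_pct),
    stringsAsFactors = FALSE)
  utils::write.table(by_mode, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$comparisons, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
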