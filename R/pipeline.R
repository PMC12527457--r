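#' Orchestrated end-to-end screen from files on disk
#'
#' Reads every input format, runs [poi_screen()], and writes the findings
#' TSV, kindred findings TSV and the JSON run log to `out_dir`. The
#' function-level equivalent of a `screen` subcommand; all thresholds come
#' from one config file, overridable by the `cfg` argument.
#'
#' @param vcf Path to the cohort VCF (or `NULL` if `calls` given directly).
#' @param annotations Path to the annotation TSV.
#' @param pedigree Path to the pedigree file.
#' @param panel1,panel2 Paths to the two gene-panel TSVs.
#' @param config Optional path to a YAML/JSON filter configuration.
#' @param other_phenotype Optional path to an other-phenotype gene list TSV
#'   (columns `gene`, `phenotype`).
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param cfg A [filter_config()] used when `config` is `NULL`.
#' @param calls Calls data.frame, bypassing `vcf`.
#' @return The `"poi_screen"` object, invisibly when `out_dir` is given.
#' @export
run_screen <- function(vcf = NULL, annotations, pedigree, panel1, panel2,
                       config = NULL, other_phenotype = NULL, out_dir = NULL,
                       cfg = filter_config(), calls = NULL) {
  if (is.null(calls)) {
    if (is.null(vcf)) stop("missing input: provide either a vcf path or calls")
    calls <- read_vcf(vcf)
  }
  ann <- if (is.character(annotations)) read_annotation_table(annotations) else annotations
  ped <- if (is.character(pedigree)) read_pedigree(pedigree) else pedigree
  p1 <- if (is.character(panel1)) read_gene_panel(panel1) else panel1
  p2 <- if (is.character(panel2)) read_gene_panel(panel2) else panel2
  if (!is.null(config)) cfg <- read_filter_config(config)
  other <- character()
  if (!is.null(other_phenotype)) {
    other <- if (is.character(other_phenotype)) {
      utils::read.table(other_phenotype, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)$gene
    } else other_phenotype
  }
  scr <- poi_screen(calls, ann, ped, p1, p2, cfg, other)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- merge(scr$findings, scr$labels, by = "sample_id", all.x = TRUE)
    names(f)[names(f) == "label"] <- "inheritance_label"
    write_findings(f[order(f$sample_id, f$gene), ], file.path(out_dir, "findings.tsv"))
    write_findings(scr$kindred_findings, file.path(out_dir, "kindred_findings.tsv"))
    utils::write.table(scr$enrichment, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_log(scr$log, file.path(out_dir, "run_log.json"))
    return(invisible(scr))
  }
  scr
}

#' Summarize a screen and render the report files
#'
#' @param screen A `"poi_screen"` object (or a directory produced by
#'   [run_screen()] is not supported -- summaries always derive from the
#'   in-memory object to keep counts and labels consistent).
#' @param out_dir Output directory for `summary.json`,
#'   `summary_by_category.tsv`, `summary_by_mode.tsv`, `comparisons.tsv`;
#'   `NULL` writes nothing.
#' @return The `"poi_summary"`.
#' @export
run_summarize <- function(screen, out_dir = NULL) {
  stopifnot(inherits(screen, "poi_screen"))
  s <- summary(screen)
  if (!is.null(out_dir)) render_report(s, out_dir)
  s
}

#' Generate and optionally write a synthetic cohort
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional override of `cfg$seed`.
#' @param out_dir Output directory for the bundle files; `NULL` keeps the
#'   bundle in memory only.
#' @return The `"poi_cohort_bundle"`.
#' @export
run_simulate <- function(cfg = simulation_config(), seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) cfg$seed <- seed
  bundle <- generate_cohort(cfg)
  if (!is.null(out_dir)) write_cohort_bundle(bundle, out_dir)
  bundle
}

#' Run the full pipeline on a synthetic bundle
#'
#' Convenience: screen a [generate_cohort()] bundle with its own panels and
#' other-phenotype list.
#'
#' @param bundle A `"poi_cohort_bundle"`.
#' @param cfg A [filter_config()].
#' @return A `"poi_screen"` object.
#' @export
screen_bundle <- function(bundle, cfg = filter_config()) {
  poi_screen(bundle$calls, bundle$annotations, bundle$pedigree,
             bundle$panel1, bundle$panel2, cfg,
             bundle$other_phenotype_genes$gene)
}
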