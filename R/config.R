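#' Filtering configuration
#'
#' Bundles every threshold used by the variant filtering cascade and the
#' enrichment/summary statistics. Defaults are the study settings: call
#' quality >= 20 and read depth >= 10 (inclusive), CADD > 15 (strict) with
#' 2-of-3 in-silico votes required, gnomAD minor allele frequency < 0.01%
#' (1e-4) for biallelic variants and < 0.005% (5e-5) for single heterozygous
#' or polygenic variants (strict), a 7-base intronic window for splice-site
#' loss, an adjusted-p cutoff of 1e-4 for variant enrichment and 0.05 for
#' cohort-summary comparisons.
#'
#' @param min_qual Minimum Phred-scaled call quality (inclusive).
#' @param min_depth Minimum read depth at the site (inclusive).
#' @param cadd_cutoff CADD score above which (strictly) a variant counts as
#'   one in-silico damaging vote.
#' @param insilico_votes_required Number of damaging votes (CADD, PolyPhen2,
#'   SIFT) required to retain a variant.
#' @param maf_biallelic Strict gnomAD allele-frequency upper bound for
#'   variants in a biallelic context (homozygous or probable compound het).
#' @param maf_monoallelic Strict bound for single-heterozygous/polygenic
#'   context; must not exceed `maf_biallelic`.
#' @param intronic_splice_window Bases into an intron within which splice
#'   site loss retains an otherwise-excluded synonymous/intronic change.
#' @param enrichment_alpha_adjusted BH-adjusted significance cutoff for
#'   cohort-vs-gnomAD variant enrichment.
#' @param summary_alpha Significance cutoff for cohort summary comparisons.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(min_qual = 20,
                          min_depth = 10,
                          cadd_cutoff = 15,
                          insilico_votes_required = 2,
                          maf_biallelic = 1e-4,
                          maf_monoallelic = 5e-5,
                          intronic_splice_window = 7,
                          enrichment_alpha_adjusted = 1e-4,
                          summary_alpha = 0.05) {
  cfg <- list(
    min_qual = min_qual,
    min_depth = min_depth,
    cadd_cutoff = cadd_cutoff,
    insilico_votes_required = insilico_votes_required,
    maf_biallelic = maf_biallelic,
    maf_monoallelic = maf_monoallelic,
    intronic_splice_window = intronic_splice_window,
    enrichment_alpha_adjusted = enrichment_alpha_adjusted,
    summary_alpha = summary_alpha
  )
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) stop("all filter_config fields must be numeric")
  if (any(unlist(cfg) <= 0)) stop("all filter_config thresholds must be strictly positive")
  if (cfg$maf_monoallelic > cfg$maf_biallelic) {
    stop("maf_monoallelic must not exceed maf_biallelic")
  }
  structure(cfg, class = "filter_config")
}

#' Read a filtering configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file keying
#'   [filter_config()] fields.
#' @return A `"filter_config"` object.
#' @export
read_filter_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    vals <- yaml::read_yaml(path)
  }
  known <- names(formals(filter_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown filter_config keys: ", paste(bad, collapse = ", "))
  do.call(filter_config, vals)
}

#' Write a filtering configuration to YAML
#'
#' @param cfg A `"filter_config"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "filter_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Variant filter configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}
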