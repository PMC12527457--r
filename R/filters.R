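#' Call-quality filter
#'
#' A call is kept when its Phred-scaled quality and read depth both meet
#' their inclusive minima (defaults: quality >= 20, depth >= 10). Missing
#' quality or depth fails conservatively.
#'
#' @param qual,depth Numeric call quality and read depth.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
passes_quality <- function(qual, depth, cfg = filter_config()) {
  ok <- !is.na(qual) & !is.na(depth) & qual >= cfg$min_qual & depth >= cfg$min_depth
  ok
}

#' In-silico deleteriousness vote (2-of-3 rule)
#'
#' Counts damaging verdicts from CADD (strictly above the cutoff, default
#' > 15), PolyPhen2 and SIFT; missing verdicts count as non-votes. A variant
#' carrying the established-POI allowlist flag bypasses the vote entirely.
#'
#' @param cadd Numeric CADD score (NA allowed).
#' @param polyphen_damaging,sift_deleterious Logical verdicts (NA allowed).
#' @param established_pathogenic Logical allowlist flag.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
insilico_deleterious <- function(cadd, polyphen_damaging, sift_deleterious,
                                 established_pathogenic = FALSE,
                                 cfg = filter_config()) {
  votes <- (!is.na(cadd) & cadd > cfg$cadd_cutoff) +
    (!is.na(polyphen_damaging) & polyphen_damaging) +
    (!is.na(sift_deleterious) & sift_deleterious)
  established_pathogenic | votes >= cfg$insilico_votes_required
}

#' Rarity filter with zygosity-dependent thresholds
#'
#' Strict comparison of the gnomAD allele frequency against the context
#' threshold: < 0.01% (1e-4) for biallelic context (homozygous or probable
#' compound-het member), < 0.005% (5e-5) for single-heterozygous/polygenic
#' context. Variants absent from gnomAD (frequency 0 or missing) count as
#' novel and pass.
#'
#' @param gnomad_af Numeric population allele frequency in `[0,1]`.
#' @param context `"biallelic"` or `"monoallelic"` (recycled).
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
passes_rarity <- function(gnomad_af, context, cfg = filter_config()) {
  stopifnot(all(context %in% c("biallelic", "monoallelic")))
  thr <- ifelse(context == "biallelic", cfg$maf_biallelic, cfg$maf_monoallelic)
  is.na(gnomad_af) | gnomad_af < thr
}

#' Synonymous / splice retention rule
#'
#' Synonymous changes are excluded unless associated with splice-site loss
#' up to `intronic_splice_window` bases into an intron, or predicted to
#' affect splicing. Concretely: non-synonymous, non-intronic consequences
#' pass (the rule does not apply); intronic or splice-site calls pass when
#' the intron offset lies within the window or a splice-loss prediction is
#' set; exonic synonymous calls pass only with a splice-loss prediction.
#'
#' @param consequence Consequence token (see [read_annotation_table()]).
#' @param intron_offset Signed distance into the intron (0 for exonic).
#' @param splice_loss_predicted Logical prediction (NA allowed, counts as
#'   no prediction).
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
synonymous_retention <- function(consequence, intron_offset, splice_loss_predicted,
                                 cfg = filter_config()) {
  pred <- !is.na(splice_loss_predicted) & splice_loss_predicted
  intronish <- consequence %in% c("intronic", "splice_site")
  ifelse(consequence == "synonymous", pred,
         ifelse(intronish,
                abs(intron_offset) <= cfg$intronic_splice_window | pred,
                TRUE))
}

#' ACMG class retention
#'
#' Only variants classified Pathogenic or Likely Pathogenic are retained;
#' a missing class fails conservatively.
#'
#' @param acmg_class Class token (`P`, `LP`, `VUS`, `LB`, `B`, or NA).
#' @return Logical vector.
#' @export
acmg_retained <- function(acmg_class) {
  !is.na(acmg_class) & acmg_class %in% c("P", "LP")
}

#' Run the full filtering cascade on one annotated call
#'
#' Stages are evaluated in the printed order: quality, in-silico, rarity,
#' synonymous/splice, ACMG. All stages are always evaluated (so
#' `failed_stages` may list several); passing requires all of them. The
#' established-POI allowlist flag bypasses every retention stage except the
#' unconditional quality filter.
#'
#' @param call A one-row annotated call (list or data.frame row) carrying
#'   `qual, depth, cadd, polyphen_damaging, sift_deleterious, gnomad_af,
#'   consequence, intron_offset, splice_loss_predicted, acmg_class,
#'   established_pathogenic`.
#' @param context `"biallelic"` or `"monoallelic"` rarity context.
#' @param cfg A [filter_config()].
#' @return List of class `"filter_verdict"` with `passed`, `failed_stages`
#'   (ordered subset of quality, insilico, rarity, synonymous_splice, acmg)
#'   and `bypass_used`.
#' @export
run_filter_cascade <- function(call, context, cfg = filter_config()) {
  call <- as.list(call)
  bypass <- isTRUE(as.logical(call$established_pathogenic))
  stage <- c(
    quality = passes_quality(call$qual, call$depth, cfg),
    insilico = bypass || insilico_deleterious(call$cadd, call$polyphen_damaging,
                                              call$sift_deleterious, FALSE, cfg),
    rarity = bypass || passes_rarity(call$gnomad_af, context, cfg),
    synonymous_splice = bypass || synonymous_retention(call$consequence,
                                                       call$intron_offset,
                                                       call$splice_loss_predicted, cfg),
    acmg = bypass || acmg_retained(call$acmg_class)
  )
  structure(list(passed = all(stage),
                 failed_stages = names(stage)[!stage],
                 bypass_used = bypass),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat("Filter verdict:", if (x$passed) "PASSED" else "failed", "\n")
  if (length(x$failed_stages)) cat("  failed stages:", paste(x$failed_stages, collapse = ", "), "\n")
  if (x$bypass_used) cat("  established-POI bypass used\n")
  invisible(x)
}

# Vectorized evaluation of the non-rarity stages over an annotated-call
# data.frame; returns a logical matrix with one column per stage.
.stage_matrix <- function(df, cfg) {
  bypass <- !is.na(df$established_pathogenic) & df$established_pathogenic
  cbind(
    quality = passes_quality(df$qual, df$depth, cfg),
    insilico = bypass | insilico_deleterious(df$cadd, df$polyphen_damaging,
                                             df$sift_deleterious, FALSE, cfg),
    synonymous_splice = bypass | synonymous_retention(df$consequence, df$intron_offset,
                                                      df$splice_loss_predicted, cfg),
    acmg = bypass | acmg_retained(df$acmg_class)
  )
}
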