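#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Full hypergeometric enumeration with the point-probability
#' ("minimum-likelihood") two-sided rule: the p-value is the sum of the
#' probabilities of all tables sharing the observed margins whose point
#' probability does not exceed that of the observed table. A relative tie
#' tolerance of 1e-7 absorbs floating-point near-ties, the convention of
#' mainstream statistical software.
#'
#' @param a,b,c,d Nonnegative integer cell counts (row 1 = group 1
#'   event/non-event, row 2 = group 2 event/non-event). Alternatively pass
#'   a 2x2 matrix as `a`.
#' @return The two-sided p-value in `[0, 1]`.
#' @export
fisher_exact_two_tailed <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers")
  }
  if (sum(cells) == 0) stop("all-zero table has no defined test")
  m <- a + b          # row-1 margin
  n2 <- c + d         # row-2 margin
  k <- a + c          # column-1 margin
  support <- max(0L, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); adjusted values are returned in input order,
#' capped at 1.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]`.
#' @return Adjusted probabilities, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cohort-versus-population variant enrichment
#'
#' For each variant, builds the 2x2 allele-count table
#' `[[cohort_ac, cohort_an - cohort_ac], [pop_ac, pop_an - pop_ac]]`,
#' computes the two-tailed Fisher exact p-value, and adjusts batch-wise by
#' Benjamini-Hochberg over all variants tested in the run. A variant is
#' significant when its adjusted p falls below
#' `cfg$enrichment_alpha_adjusted` (default 1e-4).
#'
#' @param variant_keys Identifiers (one per variant).
#' @param cohort_ac,cohort_an Cohort allele counts and numbers.
#' @param pop_ac,pop_an Population (gnomAD-style) allele counts and numbers.
#' @param cfg A [filter_config()].
#' @return Data.frame: `variant_key, cohort_ac, cohort_an, pop_ac, pop_an,
#'   p_raw, p_adjusted, significant`.
#' @export
variant_enrichment <- function(variant_keys, cohort_ac, cohort_an, pop_ac, pop_an,
                               cfg = filter_config()) {
  n <- length(variant_keys)
  stopifnot(length(cohort_ac) == n, length(cohort_an) == n,
            length(pop_ac) == n, length(pop_an) == n)
  bad <- which(cohort_an <= 0 | pop_an <= 0 | cohort_ac > cohort_an | pop_ac > pop_an |
                 cohort_ac < 0 | pop_ac < 0)
  if (length(bad)) {
    stop("invalid allele counts for variant(s): ",
         paste(variant_keys[bad], collapse = ", "))
  }
  p_raw <- vapply(seq_len(n), function(i) {
    fisher_exact_two_tailed(cohort_ac[i], cohort_an[i] - cohort_ac[i],
                            pop_ac[i], pop_an[i] - pop_ac[i])
  }, numeric(1))
  p_adj <- bh_adjust(p_raw)
  data.frame(variant_key = variant_keys,
             cohort_ac = cohort_ac, cohort_an = cohort_an,
             pop_ac = pop_ac, pop_an = pop_an,
             p_raw = p_raw, p_adjusted = p_adj,
             significant = p_adj < cfg$enrichment_alpha_adjusted,
             stringsAsFactors = FALSE)
}
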