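#' Single-sample gene-set enrichment score
#'
#' Rank-based weighted Kolmogorov-Smirnov-style statistic of a gene set
#' within one profile (here, a marker-gene deviation vector).  Genes are
#' ranked by decreasing value; walking down the ranking, set members add
#' their rank statistic (the midrank; the largest value has rank n)
#' raised to `alpha` and normalised by the in-set total (uniform weights
#' when the in-set total is zero), and non-members subtract `1/(n - k)`.
#' The
#' score is the sum of the running difference over all positions, i.e.
#' the integral of the running sum.
#'
#' Tied values are handled symmetrically: a block of tied genes
#' contributes the average of the running sum over all orderings within
#' the block, so the score does not depend on input order.  In particular
#' an all-zero profile scores 0 for every gene set.
#'
#' @param values Named numeric vector (the profile over the gene universe).
#' @param gene_set Character vector of set members; must overlap `values`.
#' @param alpha Weighting exponent on the rank statistic (default 0.25).
#' @return A single numeric score.
#' @export
#' @examples
#' v <- c(a = 10, b = 5, c = 2, d = 1)
#' ssgsea_score(v, "a", alpha = 0)  # 2.0
ssgsea_score <- function(values, gene_set, alpha = 0.25) {
  stopifnot(is.numeric(values))
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort("`values` must be named with unique gene identifiers")
  }
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) abort("`gene_set` is empty")
  hit <- names(values) %in% gene_set
  k <- sum(hit)
  n <- length(values)
  if (k == 0) abort("no gene of `gene_set` is present in `values`")
  stat <- rank(values) # midranks; ties share a rank
  o <- order(values, decreasing = TRUE)
  v <- values[o]
  h <- hit[o]
  w <- stat[o]^alpha
  hw <- ifelse(h, w, 0)
  tot <- sum(hw)
  inc <- if (tot > 0) hw / tot else ifelse(h, 1 / k, 0)
  if (k < n) inc <- inc - ifelse(h, 0, 1 / (n - k))
  # tie blocks: average the running sum over within-block orderings
  blk <- cumsum(!duplicated(v))
  blk_tot <- rowsum(inc, blk)[, 1]
  blk_len <- tabulate(blk)
  pre <- cumsum(c(0, blk_tot))[seq_along(blk_tot)]
  sum(blk_len * pre + (blk_tot / blk_len) * blk_len * (blk_len + 1) / 2)
}
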