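# Per-construct enrichment scoring and empirical FDR from double
# non-targeting controls (DNTC). The score is the mean log2 fold change of a
# construct over all selected post-co-culture samples versus the
# pre-selection reference; the q value compares, at every candidate score
# threshold, the rate of DNTCs above the threshold (with a +1 pseudocount)
# to the rate of all constructs above it. Enrichment is one-sided: the
# screen selects for resistance, i.e. positive log2 fold change.

#' Mean enrichment score per construct
#'
#' Mean over the selected post-co-culture samples of the log2 fold change
#' versus the reference selection, i.e. the score averaged across all
#' replicates, E:T ratios and screens in the selection.
#'
#' @param nm A `normalized_matrix`.
#' @param post Post-co-culture sample selection (ids or logical mask).
#' @param reference Reference selection (typically the pre-selection sample).
#' @return Named numeric score vector over constructs.
#' @export
average_enrichment <- function(nm, post, reference) {
  log2fc(nm, post, reference)
}

#' Empirical FDR from non-targeting controls
#'
#' For each candidate threshold t (every observed score),
#' `FDRhat(t) = [(#DNTC >= t + 1) / (#DNTC + 1)] / [(#all >= t) / #all]`,
#' clipped to [0, 1]. The q value of a construct is the minimum of
#' `FDRhat` over all thresholds at or below its score, which makes q
#' non-increasing in score. The +1 pseudocount keeps the estimator
#' conservative; its resolution is limited by the number of controls
#' (the smallest attainable q is about `#all / ((#DNTC + 1) * #calls)`).
#'
#' @param scores Numeric score vector.
#' @param is_dntc Logical mask marking the double non-targeting controls;
#'   must select at least one construct and not all of them.
#' @return Numeric q vector in [0, 1], same order as `scores`.
#' @export
empirical_fdr <- function(scores, is_dntc) {
  stopifnot(length(scores) == length(is_dntc), is.logical(is_dntc),
            all(is.finite(scores)))
  if (!any(is_dntc)) fail("at least one DNTC control is required")
  if (all(is_dntc)) fail("DNTCs must be a strict subset of constructs")
  n <- length(scores)
  nd <- sum(is_dntc)

  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  d <- is_dntc[o]
  # unique thresholds in decreasing order; counts of scores >= each threshold
  last_of_tie <- c(s[-1] != s[-n], TRUE)
  n_ge_all <- which(last_of_tie)                 # cumulative count at each unique value
  n_ge_dntc <- cumsum(d)[last_of_tie]
  fdr_hat <- pmin(1, ((n_ge_dntc + 1) / (nd + 1)) / (n_ge_all / n))
  # q at a unique threshold = min FDRhat over this and every lower threshold
  q_unique <- rev(cummin(rev(fdr_hat)))
  ut <- s[last_of_tie]
  q <- q_unique[match(scores, ut)]
  q
}

#' Build a per-construct enrichment table
#'
#' Scores every construct with [average_enrichment()], attaches category and
#' gene pair from the library, computes DNTC-based q values, and flags
#' enrichment at the stated FDR.
#'
#' @param nm A `normalized_matrix` over the library's constructs.
#' @param lib The `dual_library`.
#' @param post,reference Sample selections passed to [average_enrichment()].
#' @param fdr FDR threshold for the `enriched` flag.
#' @return An `enrichment_table` data frame: `construct_id`, `category`,
#'   `gene1`, `gene2`, `score`, `q`, `enriched`.
#' @export
enrichment_table <- function(nm, lib, post, reference, fdr = 0.05) {
  stopifnot(identical(rownames(nm$values), lib$constructs$construct_id))
  score <- average_enrichment(nm, post, reference)
  q <- empirical_fdr(score, lib$constructs$category == "DNTC")
  out <- data.frame(construct_id = lib$constructs$construct_id,
                    category = lib$constructs$category,
                    gene1 = lib$constructs$gene1, gene2 = lib$constructs$gene2,
                    score = unname(score), q = q, enriched = q <= fdr,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "fdr") <- fdr
  out
}

#' Call enriched constructs at an FDR threshold
#'
#' @param et An [enrichment_table()].
#' @param fdr_threshold q-value cutoff; raising it never removes a call.
#' @return List with `construct_ids` (the enriched set) and `census`
#'   (counts by category plus totals).
#' @export
call_enriched <- function(et, fdr_threshold = attr(et, "fdr") %||% 0.05) {
  hit <- et$q <= fdr_threshold
  census <- list(
    n_enriched = sum(hit),
    n_total = nrow(et),
    by_category = as.list(table(factor(et$category[hit], levels = CONSTRUCT_CATEGORIES)))
  )
  list(construct_ids = et$construct_id[hit], census = census)
}

#' Fraction of enriched constructs associated with watch-list genes
#'
#' Counts a construct as associated when either slot gene is in
#' `watch_genes` (so both DKO and SKO constructs of a watched gene count).
#'
#' @param et An [enrichment_table()] with the `enriched` flag set, or the
#'   output of [call_enriched()] together with `lib`.
#' @param watch_genes Character vector of gene symbols.
#' @param fdr_threshold Optional override of the table's threshold.
#' @return Fraction in [0, 1]; `NA` with a warning when nothing is enriched
#'   (and 0 whenever `watch_genes` is empty).
#' @export
gene_association_fraction <- function(et, watch_genes,
                                      fdr_threshold = attr(et, "fdr") %||% 0.05) {
  hit <- et[et$q <= fdr_threshold, , drop = FALSE]
  if (!length(watch_genes)) return(0)
  if (!nrow(hit)) {
    warn("no enriched constructs at q <= %g", fdr_threshold)
    return(NA_real_)
  }
  mean(hit$gene1 %in% watch_genes | hit$gene2 %in% watch_genes)
}

#' Summarize scores per gene pair
#'
#' Collapses construct-level scores to one summary per gene pair (NTC slots
#' included, so single-knockout "pairs" appear as (gene, NTC)). The default
#' summary is the median across member constructs, robust to a single bad
#' guide combination.
#'
#' @param et An [enrichment_table()] (or data frame with `gene1`, `gene2`,
#'   `category`, `score`).
#' @param stat `"median"` (default) or `"mean"`.
#' @return Data frame: `gene1`, `gene2`, `category`, `summary`, `n_members`.
#' @export
gene_pair_summary <- function(et, stat = c("median", "mean")) {
  stat_fun <- switch(match.arg(stat), median = stats::median, mean = mean)
  key <- paste(et$gene1, et$gene2, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(gene1 = et$gene1[first], gene2 = et$gene2[first],
                    category = et$category[first],
                    summary = as.numeric(tapply(et$score, key, stat_fun)[key[first]]),
                    n_members = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
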