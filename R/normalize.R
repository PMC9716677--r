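# Count normalization and screen QC: counts-per-million + log2 with a
# pseudocount, per-construct log2 fold changes, sample-level PCA and
# correlation clustering, titration multiple t tests with FDR, and Tukey
# box statistics for construct-level count displays.

#' Assemble a count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, constructs x samples, with
#'   construct ids as rownames.
#' @param samples Data frame with one row per column of `counts`:
#'   `sample_id` (matching colnames), `condition` (one of `plasmid`,
#'   `pre_selection`, `post_coculture`), `et_ratio`, `replicate`, `screen`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) fail("counts must have construct ids as rownames")
  if (any(counts < 0) || any(counts != round(counts))) fail("counts must be non-negative integers")
  stopifnot(is.data.frame(samples), nrow(samples) == ncol(counts))
  required <- c("sample_id", "condition")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) fail("samples is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (!all(samples$condition %in% c("plasmid", "pre_selection", "post_coculture")))
    fail("unknown condition label in samples")
  if (anyDuplicated(samples$sample_id)) fail("duplicate sample_id")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id))
    fail("colnames(counts) must equal samples$sample_id")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
as.count_matrix <- function(x, ...) UseMethod("as.count_matrix")

#' @export
as.count_matrix.screen_counts <- function(x, ...) count_matrix(x$counts, x$samples)

#' @export
as.count_matrix.count_matrix <- function(x, ...) x

#' CPM + log2 normalization
#'
#' Scales every sample column to one million total reads, then takes
#' `log2(x + pseudocount)`. Column sums before the log equal 1e6 by
#' construction, and doubling all counts in a sample leaves its normalized
#' values unchanged.
#'
#' @param cm A [count_matrix()] (or `screen_counts`).
#' @param pseudocount Added before the log; default 1.
#' @return A `normalized_matrix`: list with `values` (log2 CPM matrix),
#'   `pseudocount`, and the `samples` metadata.
#' @export
cpm_log_normalize <- function(cm, pseudocount = 1) {
  cm <- as.count_matrix(cm)
  sums <- colSums(cm$counts)
  if (any(sums == 0))
    fail("all-zero sample column(s): %s",
         paste(cm$samples$sample_id[sums == 0], collapse = ", "))
  cpm <- sweep(cm$counts, 2L, sums / 1e6, "/")
  structure(list(values = log2(cpm + pseudocount), pseudocount = pseudocount,
                 samples = cm$samples),
            class = "normalized_matrix")
}

resolve_samples <- function(nm, sel) {
  ids <- nm$samples$sample_id
  if (is.logical(sel)) {
    stopifnot(length(sel) == length(ids))
    sel <- ids[sel]
  }
  if (!length(sel)) fail("empty sample selection")
  unknown <- setdiff(sel, ids)
  if (length(unknown)) fail("unknown sample(s): %s", paste(unknown, collapse = ", "))
  sel
}

#' Sample ids matching metadata filters
#'
#' Convenience selector over the sample sheet, e.g.
#' `select_samples(nm, condition = "post_coculture", et_ratio = 5)`.
#'
#' @param nm A `normalized_matrix` or `count_matrix`.
#' @param condition,et_ratio,replicate,screen Optional filters; `NULL` means
#'   no constraint on that field.
#' @return Character vector of sample ids.
#' @export
select_samples <- function(nm, condition = NULL, et_ratio = NULL,
                           replicate = NULL, screen = NULL) {
  s <- nm$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(condition)) keep <- keep & s$condition %in% condition
  if (!is.null(et_ratio)) keep <- keep & !is.na(s$et_ratio) & s$et_ratio %in% et_ratio
  if (!is.null(replicate)) keep <- keep & !is.na(s$replicate) & s$replicate %in% replicate
  if (!is.null(screen)) keep <- keep & !is.na(s$screen) & s$screen %in% screen
  s$sample_id[keep]
}

#' Per-construct log2 fold change between sample selections
#'
#' `mean(log2 values over samples) - mean(log2 values over reference)` per
#' construct, on the normalized (log2 CPM) scale.
#'
#' @param nm A `normalized_matrix`.
#' @param samples,reference Sample selections (character ids or logical mask).
#' @return Named numeric vector over constructs.
#' @export
log2fc <- function(nm, samples, reference) {
  s <- resolve_samples(nm, samples)
  r <- resolve_samples(nm, reference)
  rowMeans(nm$values[, s, drop = FALSE]) - rowMeans(nm$values[, r, drop = FALSE])
}

#' PCA of samples on log2 CPM values
#'
#' Values are centered per construct (no scaling) and samples are projected
#' onto the principal components; with strong selection the post-co-culture
#' samples separate from pre-selection/plasmid along PC1.
#'
#' @param nm A `normalized_matrix` with at least two samples.
#' @param n_components Components to keep; reduced with a warning when more
#'   are requested than exist.
#' @return List with `coords` (data frame: sample_id, condition, PC columns)
#'   and `var_explained` (non-increasing, sums to at most 1).
#' @export
pca_samples <- function(nm, n_components = 2) {
  n_samp <- ncol(nm$values)
  if (n_samp < 2) fail("PCA requires at least two samples")
  k_max <- min(n_samp, nrow(nm$values))
  if (n_components > k_max) {
    warn("reducing n_components from %d to %d", n_components, k_max)
    n_components <- k_max
  }
  centered <- nm$values - rowMeans(nm$values)
  p <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(n_components)
  coords <- data.frame(sample_id = nm$samples$sample_id,
                       condition = nm$samples$condition,
                       p$x[, k, drop = FALSE], stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  list(coords = coords, var_explained = ve[k])
}

#' Average-linkage clustering of samples on 1 - Pearson correlation
#'
#' @param nm A `normalized_matrix` with at least two samples.
#' @return List with `hclust` (the dendrogram), `dist` (the distance object)
#'   and the sample metadata. Cutting at k = 2 on a strong-selection screen
#'   separates post-co-culture samples from plasmid/pre-selection.
#' @export
correlation_clustering <- function(nm) {
  if (ncol(nm$values) < 2) fail("clustering requires at least two samples")
  sds <- apply(nm$values, 2L, stats::sd)
  if (any(sds == 0))
    fail("constant sample vector(s), correlation undefined: %s",
         paste(nm$samples$sample_id[sds == 0], collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(nm$values))
  list(hclust = stats::hclust(d, method = "average"), dist = d,
       samples = nm$samples)
}

#' Adjust p values (Bonferroni, BH, or two-stage adaptive BH)
#'
#' `bonferroni` is `min(1, m * p)`; `bh` the Benjamini-Hochberg step-up;
#' `two_stage` the two-stage step-up: the number of true nulls `m0` is first
#' estimated as `m` minus the BH rejections at level `alpha / (1 + alpha)`,
#' then BH-adjusted values are scaled by `m0 / m`. When the first stage finds
#' no discoveries the estimated null fraction is 1 and the result reduces to
#' plain BH.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @param method One of `"bh"`, `"bonferroni"`, `"two_stage"`.
#' @param alpha Target FDR level used by the first stage of `two_stage`.
#' @return Adjusted values in [0, 1], order-preserving within method.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "two_stage"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) fail("p values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  switch(method,
    bonferroni = stats::p.adjust(p, method = "bonferroni"),
    bh = stats::p.adjust(p, method = "BH"),
    two_stage = {
      bh <- stats::p.adjust(p, method = "BH")
      r1 <- sum(bh <= alpha / (1 + alpha))
      m0 <- if (r1 == 0) m else max(m - r1, 1L)
      pmin(1, bh * m0 / m)
    }
  )
}

#' Row-wise multiple t tests on a titration table
#'
#' One two-sided two-sample t test per E:T ratio comparing the two groups'
#' replicate survival fractions (pooled variance by default, Welch via
#' `var_equal = FALSE`), with q values from the two-stage step-up FDR across
#' ratios and a significance flag at `fdr_q`.
#'
#' @param titration Data frame with columns `et_ratio`, `group` (exactly two
#'   levels, e.g. library vs parental) and `survival` (fractions relative to
#'   the no-T-cell control; values in [0, 1.5]).
#' @param fdr_q Target FDR level for flagging.
#' @param var_equal Pooled-variance t test when `TRUE` (default).
#' @return Data frame with one row per tested E:T ratio: `et_ratio`, group
#'   means, `t`, `p`, `q`, `significant`. Ratios with fewer than two
#'   replicates in either group are skipped with a warning.
#' @export
multiple_t_tests <- function(titration, fdr_q = 0.01, var_equal = TRUE) {
  stopifnot(all(c("et_ratio", "group", "survival") %in% names(titration)))
  groups <- sort(unique(titration$group))
  if (length(groups) != 2) fail("titration must contain exactly two groups")
  if (any(titration$survival < 0 | titration$survival > 1.5))
    warn("survival fractions outside [0, 1.5]")
  ratios <- sort(unique(titration$et_ratio))
  rows <- lapply(ratios, function(et) {
    x <- titration$survival[titration$et_ratio == et & titration$group == groups[1]]
    y <- titration$survival[titration$et_ratio == et & titration$group == groups[2]]
    if (length(x) < 2 || length(y) < 2) {
      warn("skipping E:T ratio %g: fewer than 2 replicates in a group", et)
      return(NULL)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(et_ratio = et, mean_group1 = mean(x), mean_group2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) fail("no testable E:T ratios")
  out$q <- adjust_pvalues(out$p, "two_stage", alpha = fdr_q)
  out$significant <- out$q <= fdr_q
  rownames(out) <- NULL
  out
}

#' Tukey box statistics
#'
#' Quartiles by linear interpolation (R's default quantile type 7; box-plot
#' quartile conventions differ across software, this one is documented and
#' fixed), whiskers at the most extreme data within 1.5 x IQR of the box,
#' and everything beyond counted as outliers.
#'
#' @param values Numeric vector.
#' @param groups Optional grouping vector (same length); `NULL` treats all
#'   values as one group. Empty groups are skipped with a warning.
#' @return Data frame with columns `group`, `n`, `lower_whisker`, `q1`,
#'   `median`, `q3`, `upper_whisker`, `n_outliers`; the outlying values per
#'   group are attached as the `"outliers"` attribute (a named list).
#' @export
tukey_boxstats <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(values))
  groups <- as.factor(groups)
  out <- list()
  outliers <- list()
  for (g in levels(groups)) {
    v <- values[groups == g & !is.na(values)]
    if (!length(v)) {
      warn("skipping empty group '%s'", g)
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    out[[g]] <- data.frame(group = g, n = length(v),
                           lower_whisker = min(inside), q1 = q[1], median = q[2],
                           q3 = q[3], upper_whisker = max(inside),
                           n_outliers = sum(v < lo_fence | v > hi_fence),
                           stringsAsFactors = FALSE)
    outliers[[g]] <- v[v < lo_fence | v > hi_fence]
  }
  if (!length(out)) fail("no non-empty groups")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "outliers") <- outliers
  res
}
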