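# Genetic-interaction calling. The additive (log-scale) null says a double
# knockout's enrichment should equal the sum of its two single knockouts'
# enrichments. Observed DKO summaries are regressed on that expectation by
# ordinary least squares (the fitted slope/intercept absorb global
# attenuation such as guide-efficiency dilution), every pair's externally
# studentized residual is computed by the standard leave-one-out closed
# form, and a Bonferroni-adjusted two-sided t outlier test flags pairs whose
# observed enrichment departs from expectation: positive residuals are
# additive interactions, negative ones subtractive.

#' Per-gene single-knockout summary scores
#'
#' For every slot-1 gene, the summary (median by default) of its SKO_POS1
#' construct scores; likewise slot-2 genes over SKO_POS2 constructs.
#'
#' @param et An [enrichment_table()] (construct-level scores).
#' @param stat `"median"` or `"mean"`.
#' @return List with named vectors `pos1` and `pos2`.
#' @export
sko_gene_scores <- function(et, stat = c("median", "mean")) {
  stat_fun <- switch(match.arg(stat), median = stats::median, mean = mean)
  s1 <- et[et$category == "SKO_POS1", ]
  s2 <- et[et$category == "SKO_POS2", ]
  list(pos1 = tapply(s1$score, s1$gene1, stat_fun),
       pos2 = tapply(s2$score, s2$gene2, stat_fun))
}

#' Observed and expected DKO scores per gene pair
#'
#' Observed = summary of the pair's DKO construct scores; expected =
#' SKO summary of gene 1 plus SKO summary of gene 2 (the log-additive
#' null). Pairs missing either constituent SKO summary are excluded and
#' reported via the `"excluded"` attribute.
#'
#' @param et An [enrichment_table()].
#' @param stat Summary statistic, `"median"` (default) or `"mean"`.
#' @return Data frame: `gene1`, `gene2`, `observed`, `expected`,
#'   `n_constructs`.
#' @export
expected_additive <- function(et, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  sko <- sko_gene_scores(et, stat)
  dko <- gene_pair_summary(et[et$category == "DKO", , drop = FALSE], stat)
  out <- data.frame(gene1 = dko$gene1, gene2 = dko$gene2,
                    observed = dko$summary,
                    expected = as.numeric(sko$pos1[dko$gene1] + sko$pos2[dko$gene2]),
                    n_constructs = dko$n_members, stringsAsFactors = FALSE)
  drop <- !is.finite(out$expected)
  if (any(drop)) {
    warn("excluding %d pair(s) with missing SKO summaries", sum(drop))
  }
  excluded <- out[drop, c("gene1", "gene2")]
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Fit observed DKO scores on the additive expectation
#'
#' Ordinary least squares of observed on {intercept, expected}. The fit
#' stores residuals, leverages and the residual scale needed for external
#' studentization.
#'
#' @param observed,expected Numeric vectors (n >= 4, finite, and `expected`
#'   not constant).
#' @return An `oe_fit` list: `n`, `p` (2), `coefficients`, `fitted`,
#'   `residuals`, `leverage`, `sigma`.
#' @export
fit_observed_vs_expected <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (length(observed) < 4) fail("at least 4 pairs are required for the fit")
  if (!all(is.finite(observed)) || !all(is.finite(expected))) fail("non-finite values in fit input")
  if (stats::sd(expected) == 0) fail("degenerate design: expected scores are constant")
  fit <- stats::lm(observed ~ expected)
  n <- length(observed)
  p <- 2L
  e <- unname(stats::residuals(fit))
  structure(list(n = n, p = p,
                 coefficients = stats::coef(fit),
                 fitted = unname(stats::fitted(fit)),
                 residuals = e,
                 leverage = unname(stats::hatvalues(fit)),
                 sigma = sqrt(sum(e^2) / (n - p))),
            class = "oe_fit")
}

#' Externally studentized residuals
#'
#' `t_i = e_i / (s_(i) * sqrt(1 - h_ii))`, where `s_(i)` is the residual
#' scale of the fit excluding point i, computed by the standard closed form
#' `s_(i)^2 = (SSE - e_i^2 / (1 - h_ii)) / (n - p - 1)` rather than literal
#' refitting. Exact leverage points (`h_ii` ~ 1) have no defined residual
#' and are returned as `NA` with a warning.
#'
#' @param fit An [fit_observed_vs_expected()] result with `n > p + 1`.
#' @return Numeric vector of studentized residuals.
#' @export
studentized_residuals <- function(fit) {
  n <- fit$n; p <- fit$p
  if (n <= p + 1) fail("external studentization requires n > p + 1")
  e <- fit$residuals
  h <- fit$leverage
  sse <- sum(e^2)
  # numerically exact fit: all residuals are zero by construction
  if (sqrt(sse) <= 1e-12 * (sqrt(sum(fit$fitted^2)) + 1))
    return(rep(0, n))
  bad <- h > 1 - 1e-10
  if (any(bad)) warn("%d exact leverage point(s): studentized residual undefined", sum(bad))
  s2_loo <- (sse - e^2 / (1 - h)) / (n - p - 1)
  s2_loo <- pmax(s2_loo, 0)
  t <- e / sqrt(s2_loo * (1 - h))
  t[bad] <- NA_real_
  t
}

#' Bonferroni outlier test on studentized residuals
#'
#' Two-sided tail of the t distribution with `n - p - 1` degrees of freedom,
#' Bonferroni-adjusted by the family size `n` (kept at the full number of
#' tested pairs even when some residuals are missing — conservative).
#'
#' @param t Externally studentized residuals.
#' @param n Number of points in the regression (family size).
#' @param p Number of fitted parameters including the intercept.
#' @return Data frame with `p_raw` and `p_bonferroni` per point.
#' @export
bonferroni_outlier_test <- function(t, n, p = 2) {
  df <- n - p - 1
  if (df < 1) fail("outlier test requires n - p - 1 >= 1 degrees of freedom")
  p_raw <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  data.frame(p_raw = p_raw, p_bonferroni = pmin(1, n * p_raw))
}

#' Classify gene pairs as additive / subtractive / none
#'
#' Additive: residual > 0 and Bonferroni-adjusted p <= alpha (the double
#' knockout is more enriched than the additive expectation); subtractive:
#' residual < 0 and adjusted p <= alpha; otherwise none.
#'
#' @param residual Raw regression residuals per pair.
#' @param p_bonferroni Bonferroni-adjusted outlier p values.
#' @param alpha Significance level (default 0.001).
#' @return Character vector in {"additive", "subtractive", "none"}.
#' @export
classify_interactions <- function(residual, p_bonferroni, alpha = 0.001) {
  cls <- rep("none", length(residual))
  sig <- !is.na(p_bonferroni) & p_bonferroni <= alpha
  cls[sig & residual > 0] <- "additive"
  cls[sig & residual < 0] <- "subtractive"
  cls
}

#' Full genetic-interaction analysis
#'
#' Chains [expected_additive()], [fit_observed_vs_expected()],
#' [studentized_residuals()], [bonferroni_outlier_test()] and
#' [classify_interactions()] into one per-gene-pair table.
#'
#' @param et An [enrichment_table()] of construct-level scores (scores may be
#'   pooled across screens upstream).
#' @param alpha Significance level for classification.
#' @param stat Gene-level summary statistic (`"median"` default).
#' @return An `interaction_table` data frame: `gene1`, `gene2`, `observed`,
#'   `expected`, `residual`, `t`, `p_raw`, `p_bonferroni`, `class`,
#'   `n_constructs`; the fit is attached as attribute `"fit"`.
#' @export
interaction_analysis <- function(et, alpha = 0.001, stat = c("median", "mean")) {
  pairs <- expected_additive(et, stat = match.arg(stat))
  fit <- fit_observed_vs_expected(pairs$observed, pairs$expected)
  t <- studentized_residuals(fit)
  pv <- bonferroni_outlier_test(t, n = fit$n, p = fit$p)
  out <- data.frame(pairs[, c("gene1", "gene2", "observed", "expected")],
                    residual = fit$residuals, t = t,
                    p_raw = pv$p_raw, p_bonferroni = pv$p_bonferroni,
                    class = classify_interactions(fit$residuals, pv$p_bonferroni, alpha),
                    n_constructs = pairs$n_constructs,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "alpha") <- alpha
  out
}
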