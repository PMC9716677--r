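# Plot helpers. Every figure is drawn from data the package also returns as
# a plain data frame, so pipelines can assert on the numbers, not pixels.

#' Plot sample PCA coordinates
#'
#' @param pca Result of [pca_samples()].
#' @return A ggplot object (PC1 vs PC2, colored by condition).
#' @export
plot_sample_pca <- function(pca) {
  df <- pca$coords
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   color = .data$condition)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$var_explained[2]),
      title = "Sample PCA of log2 CPM paired-guide counts"
    ) +
    ggplot2::theme_bw()
}

#' Tukey box plot of normalized counts for one gene pair
#'
#' Shows the DKO constructs of the pair, each gene's SKO constructs and the
#' DNTCs, pre-selection versus post-co-culture, as Tukey boxes (1.5 x IQR
#' whiskers) computed with [tukey_boxstats()] and overlaid points.
#'
#' @param nm A `normalized_matrix`.
#' @param lib The matching `dual_library`.
#' @param gene1,gene2 The gene pair (slot 1, slot 2).
#' @return A ggplot object; the plotted data frame is attached as attribute
#'   `"data"`.
#' @export
plot_gene_pair_counts <- function(nm, lib, gene1, gene2) {
  cs <- lib$constructs
  grp <- rep(NA_character_, nrow(cs))
  grp[cs$gene1 == gene1 & cs$gene2 == gene2] <- paste0(gene1, "_", gene2, " DKO")
  grp[cs$gene1 == gene1 & cs$category == "SKO_POS1"] <- paste0(gene1, " SKO")
  grp[cs$gene2 == gene2 & cs$category == "SKO_POS2"] <- paste0(gene2, " SKO")
  grp[cs$category == "DNTC"] <- "DNTC"
  keep <- !is.na(grp)
  if (!any(keep)) fail("no constructs found for pair %s / %s", gene1, gene2)

  sel <- list(pre_selection = select_samples(nm, condition = "pre_selection"),
              post_coculture = select_samples(nm, condition = "post_coculture"))
  long <- do.call(rbind, lapply(names(sel), function(cond) {
    v <- rowMeans(nm$values[keep, sel[[cond]], drop = FALSE])
    data.frame(group = grp[keep], condition = cond, value = v,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL

  stats_df <- do.call(rbind, lapply(split(long, long$condition), function(d) {
    s <- tukey_boxstats(d$value, d$group)
    s$condition <- d$condition[1]
    s
  }))
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(data = stats_df,
                           ggplot2::aes(ymin = .data$lower_whisker,
                                        ymax = .data$upper_whisker), width = 0.25) +
    ggplot2::geom_crossbar(data = stats_df,
                           ggplot2::aes(y = .data$median, ymin = .data$q1,
                                        ymax = .data$q3), width = 0.6, fill = "grey90") +
    ggplot2::geom_jitter(ggplot2::aes(y = .data$value), width = 0.15, alpha = 0.5,
                         size = 0.8) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "log2 CPM",
                  title = sprintf("%s x %s construct abundances", gene1, gene2)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  attr(g, "data") <- long
  g
}
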