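# Independent oracles used to validate the package's fast implementations.
# Each oracle is a deliberately naive, brute-force computation.

# Hamming distance from one query string to each subject string (equal length)
hamming_to_all <- function(query, subjects) {
  L <- nchar(query)
  qs <- strsplit(query, "")[[1]]
  vapply(strsplit(subjects, ""), function(s) sum(s != qs), integer(1))
}

# Brute-force paired-guide matcher: nearest guide by Hamming distance within
# max_mismatch per position, ties at the minimum distance -> ambiguous.
brute_force_match <- function(r1, r2, lib, layout, max_mismatch) {
  L <- lib$metadata$spacer_length
  g1 <- lib$guides[lib$guides$position == 1, ]
  g2 <- lib$guides[lib$guides$position == 2, ]
  pair_key <- stats::setNames(lib$constructs$construct_id,
                              paste(lib$constructs$guide1_id, lib$constructs$guide2_id))
  resolve <- function(read, offset, guides) {
    if (nchar(read) < offset + L) return(NA_character_)
    sp <- substr(read, offset + 1, offset + L)
    d <- hamming_to_all(sp, guides$spacer)
    dmin <- min(d)
    if (dmin > max_mismatch) return(NA_character_)
    hits <- which(d == dmin)
    if (length(hits) > 1) return(NA_character_)   # ambiguous
    guides$guide_id[hits]
  }
  r2v <- if (layout$r2_revcomp)
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2))) else r2
  out <- data.frame(status = character(length(r1)), construct_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(r1)) {
    a <- resolve(r1[i], layout$r1_offset, g1)
    b <- resolve(r2v[i], layout$r2_offset, g2)
    if (is.na(a) || is.na(b)) {
      out$status[i] <- "unmapped"
    } else {
      cid <- pair_key[paste(a, b)]
      if (is.na(cid)) out$status[i] <- "recombinant"
      else { out$status[i] <- "mapped"; out$construct_id[i] <- unname(cid) }
    }
  }
  out
}

brute_force_counts <- function(r1, r2, lib, layout, max_mismatch) {
  calls <- brute_force_match(r1, r2, lib, layout, max_mismatch)
  counts <- stats::setNames(integer(nrow(lib$constructs)), lib$constructs$construct_id)
  tab <- table(calls$construct_id[calls$status == "mapped"])
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Literal leave-one-out studentization: refit without point i, predict it,
# and scale the prediction error. Fully independent of the closed form.
loo_studentized <- function(y, x) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    fit_i <- stats::lm(y[-i] ~ x[-i])
    s_i <- summary(fit_i)$sigma
    X_i <- cbind(1, x[-i])
    xi <- c(1, x[i])
    pred_var <- 1 + drop(t(xi) %*% solve(crossprod(X_i)) %*% xi)
    (y[i] - sum(stats::coef(fit_i) * xi)) / (s_i * sqrt(pred_var))
  }, numeric(1))
}

# OLS coefficients by explicit normal equations
normal_equations_coef <- function(y, x) {
  X <- cbind(1, x)
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

# Brute-force control-based FDR: for every construct, scan every candidate
# threshold at or below its score and take the smallest clipped rate ratio.
brute_force_fdr <- function(scores, is_dntc) {
  n <- length(scores)
  nd <- sum(is_dntc)
  thresholds <- sort(unique(scores))
  fdr_at <- vapply(thresholds, function(t) {
    min(1, ((sum(scores[is_dntc] >= t) + 1) / (nd + 1)) / (sum(scores >= t) / n))
  }, numeric(1))
  vapply(scores, function(s) min(fdr_at[thresholds <= s]), numeric(1))
}

# Hand-rolled BH step-up (cumulative minimum from the largest p)
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# 1-D silhouette for a two-group labelling of scalar coordinates
silhouette_1d <- function(x, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- x[labels == labels[i]]
    oth <- x[labels != labels[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
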