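make_cm <- function(counts, conditions = NULL) {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("c", seq_len(nrow(counts)))
  if (is.null(conditions)) conditions <- rep("post_coculture", n)
  count_matrix(counts, data.frame(sample_id = colnames(counts) %||% paste0("s", 1:n),
                                  condition = conditions, et_ratio = NA_real_,
                                  replicate = NA_integer_, screen = NA_integer_))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CPM normalization scales, conserves, and is scale invariant", {
  m <- cbind(s1 = c(1L, 1L, 2L), s2 = c(10L, 10L, 20L))
  rownames(m) <- c("a", "b", "c")
  nm <- cpm_log_normalize(make_cm(m), pseudocount = 0)
  expect_equal(2^nm$values[, "s1"], c(a = 250000, b = 250000, c = 500000))
  expect_equal(unname(colSums(2^nm$values)), c(1e6, 1e6), tolerance = 1e-9)
  # doubling all counts in a column changes nothing after normalization
  expect_equal(nm$values[, "s1"], nm$values[, "s2"])

  zero <- m; zero[, 2] <- 0L
  expect_error(cpm_log_normalize(make_cm(zero)), "s2")
})

test_that("log2fc is zero on identity and recovers known fold changes", {
  m <- cbind(s1 = c(400L, 100L, 100L), s2 = c(100L, 100L, 400L))
  rownames(m) <- c("a", "b", "c")
  nm <- cpm_log_normalize(make_cm(m), pseudocount = 1e-6)
  expect_equal(unname(log2fc(nm, "s1", "s1")), c(0, 0, 0))
  fc <- log2fc(nm, "s1", "s2")
  expect_equal(unname(fc["a"]), 2, tolerance = 1e-4)
  expect_error(log2fc(nm, "nope", "s1"), "nope")
})

test_that("sample PCA has sorted variance and is stable to construct order", {
  lib <- qc_library()
  scr <- simulate_screen(lib, screen_design(et_ratios = c(2, 5), replicates = 2,
                                            depth = 5e4),
                         qc_strong_truth(), seed = 61)
  nm <- cpm_log_normalize(scr)
  pca <- pca_samples(nm, n_components = 3)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-12)

  # identical samples land on identical coordinates
  m <- cbind(s1 = c(5L, 1L, 9L, 2L), s2 = c(5L, 1L, 9L, 2L), s3 = c(1L, 8L, 2L, 7L))
  p2 <- pca_samples(cpm_log_normalize(make_cm(m)), n_components = 2)
  expect_equal(p2$coords[1, -(1:2)], p2$coords[2, -(1:2)], ignore_attr = TRUE)

  # permuting construct rows leaves coordinates unchanged up to sign
  perm <- sample(nrow(nm$values))
  nm_perm <- nm
  nm_perm$values <- nm$values[perm, ]
  pca_perm <- pca_samples(nm_perm, n_components = 3)
  for (k in 3:5) {
    expect_equal(abs(pca_perm$coords[[k]]), abs(pca$coords[[k]]), tolerance = 1e-8)
  }

  expect_warning(pca_samples(cpm_log_normalize(make_cm(m)), n_components = 10),
                 "reducing")
})

test_that("correlation clustering merges duplicates first and rejects constants", {
  m <- cbind(s1 = c(5L, 1L, 9L, 2L), s2 = c(10L, 2L, 18L, 4L),
             s3 = c(1L, 8L, 2L, 7L), s4 = c(3L, 3L, 4L, 9L))
  nm <- cpm_log_normalize(make_cm(m))
  cl <- correlation_clustering(nm)
  d <- as.matrix(cl$dist)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  # s1 and s2 are proportional -> distance 0 -> first merge
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  const <- m; const[, 3] <- 7L
  expect_error(correlation_clustering(cpm_log_normalize(make_cm(const))), "s3")
})

test_that("titration t tests flag a separated ratio among null rows", {
  # identical groups: t = 0, p = 1, nothing flagged
  flat <- data.frame(et_ratio = rep(c(1, 2), each = 4),
                     group = rep(c("library", "library", "parental", "parental"), 2),
                     survival = rep(c(0.4, 0.6, 0.4, 0.6), 2))
  res <- multiple_t_tests(flat, fdr_q = 0.01)
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
  expect_false(any(res$significant))

  # one clearly separated ratio among six
  set.seed(403)
  tt <- null_titration()
  sep <- tt$et_ratio == 5
  tt$survival[sep] <- rep(c(0.10, 0.12, 0.11, 0.50, 0.52, 0.51), length.out = sum(sep))
  res2 <- multiple_t_tests(tt, fdr_q = 0.01)
  expect_true(res2$significant[res2$et_ratio == 5])
  expect_lt(res2$q[res2$et_ratio == 5], 0.01)
  expect_false(any(res2$significant[res2$et_ratio != 5]))

  # pooled-variance hand oracle for the separated row
  x <- tt$survival[sep & tt$group == "library"]
  y <- tt$survival[sep & tt$group == "parental"]
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res2$t[res2$et_ratio == 5], t_hand, tolerance = 1e-12)

  # under-replicated rows are skipped with a warning
  tt2 <- rbind(flat, data.frame(et_ratio = 9, group = "library", survival = 0.5))
  expect_warning(multiple_t_tests(tt2), "E:T ratio 9")
})

test_that("p-value adjustment matches hand-computed step-up and Bonferroni", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(adjust_pvalues(p, "bh"), c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(p, "bh"), bh_by_hand(p))
  set.seed(404)
  pr <- runif(50)
  expect_equal(adjust_pvalues(pr, "bh"), bh_by_hand(pr))
  expect_true(all(adjust_pvalues(pr, "bonferroni") >= pr))
  # monotone in p for every method
  o <- order(pr)
  for (m in c("bh", "bonferroni", "two_stage")) {
    expect_true(all(diff(adjust_pvalues(pr, m)[o]) >= -1e-12))
  }
  # two-stage reduces to BH when the first stage finds no discoveries
  p_null <- c(0.5, 0.6, 0.7, 0.8)
  expect_equal(adjust_pvalues(p_null, "two_stage"), adjust_pvalues(p_null, "bh"))
  # and shrinks q when it does
  p_mix <- c(1e-6, 1e-5, 0.2, 0.4)
  expect_true(all(adjust_pvalues(p_mix, "two_stage") <= adjust_pvalues(p_mix, "bh")))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("Tukey box statistics use interpolated quartiles and 1.5 IQR fences", {
  s <- tukey_boxstats(1:9)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$lower_whisker, 1)
  expect_equal(s$upper_whisker, 9)
  expect_equal(s$n_outliers, 0L)

  s2 <- tukey_boxstats(c(1:9, 100))
  expect_equal(s2$n_outliers, 1L)
  expect_equal(attr(s2, "outliers")$all, 100)

  const <- tukey_boxstats(rep(4, 6))
  expect_equal(const$q1, 4); expect_equal(const$q3, 4)
  expect_equal(const$lower_whisker, 4); expect_equal(const$upper_whisker, 4)

  one <- tukey_boxstats(7)
  expect_true(all(one[, c("lower_whisker", "q1", "median", "q3", "upper_whisker")] == 7))

  expect_warning(tukey_boxstats(c(1, 2), factor(c("a", "a"), levels = c("a", "b"))),
                 "empty group")
})
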