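test_that("plasmid abundances are normalized with the requested log dispersion", {
  lib <- toy_library()
  ab0 <- sample_plasmid_abundance(lib, sigma = 0)
  expect_equal(unname(ab0), rep(1 / 9, 9))
  expect_lt(abs(sum(sample_plasmid_abundance(1000, sigma = 1, seed = 1)) - 1), 1e-12)

  # Monte Carlo: sample SD of log-abundance tracks sigma
  for (seed in 1:10) {
    ab <- sample_plasmid_abundance(1000, sigma = 1, seed = seed)
    expect_true(sd(log(ab)) > 0.85 && sd(log(ab)) < 1.15)
  }
})

test_that("transduction allocates single-integration cells by abundance", {
  # Poisson limit: at tiny MOI essentially all infected cells are single
  moi <- 1e-6
  expect_equal(moi * exp(-moi) / (1 - exp(-moi)), 1, tolerance = 1e-5)

  des <- screen_design(moi = 0.1, coverage = 500)
  ab <- sample_plasmid_abundance(50, sigma = 0.5, seed = 2)
  singles <- round(500 * 50 * 0.1 * exp(-0.1) / (1 - exp(-0.1)))
  sims <- sapply(1:20, function(s) simulate_transduction(ab, des, seed = s))
  expect_true(all(colSums(sims) == singles))
  # empirical mean per construct tracks the multinomial mean
  expected <- singles * ab
  se <- sqrt(singles * ab * (1 - ab) / 20)
  z <- (rowMeans(sims) - expected) / se
  expect_lt(abs(z[1]), 3)
  expect_lt(max(abs(z)), 4)

  # degenerate abundance: every cell carries the single represented construct
  ab1 <- c(1, rep(0, 49))
  one <- simulate_transduction(ab1, des, seed = 3)
  expect_equal(sum(one[-1]), 0)
  expect_equal(one[1], sum(one))
})

test_that("selection survival probabilities follow the clipped log2-additive model", {
  lib <- toy_library()
  nz <- noise_model(baseline_kill = function(et) rep(0.6, length(et)),
                    selection_scale = function(et) rep(1, length(et)))
  p_null <- dkoscreen:::survival_probs(lib, fitness_truth(), nz, et_ratio = 2)
  expect_equal(unname(as.numeric(p_null)), rep(0.4, 9))

  # beta1 = 1 on the log2 scale with s = 1 doubles survival vs neutral
  tr <- fitness_truth(beta1 = c(Jak1 = 1))
  p <- dkoscreen:::survival_probs(lib, tr, nz, et_ratio = 2)
  jak1 <- lib$constructs$gene1 == "Jak1"
  expect_equal(unname(as.numeric(p[jak1]) / as.numeric(p_null[jak1])), rep(2, 3))
  expect_equal(as.numeric(p[!jak1]), as.numeric(p_null[!jak1]))

  # probabilities above 1 are clipped and counted
  tr_big <- fitness_truth(beta1 = c(Jak1 = 5))
  p_big <- dkoscreen:::survival_probs(lib, tr_big, nz, et_ratio = 2)
  expect_true(all(as.numeric(p_big) <= 1))
  expect_equal(attr(p_big, "clipped"), 3L)
})

test_that("expected enrichment of a fit construct is monotone in E:T ratio", {
  lib <- toy_library()
  nz <- noise_model()
  tr <- fitness_truth(beta1 = c(Jak1 = 2))
  ets <- c(0.1, 0.5, 1, 2, 5)
  rel <- sapply(ets, function(et) {
    p <- as.numeric(dkoscreen:::survival_probs(lib, tr, nz, et))
    p[1] / p[9]   # Jak1 DKO vs DNTC: expected post/pre enrichment ratio
  })
  expect_true(all(diff(rel) >= 0))
})

test_that("a strongly resistant gene family dominates post/pre ratios", {
  lib <- qc_library()
  des <- screen_design(et_ratios = 5, replicates = 1, depth = 2e5, coverage = 300)
  tr <- fitness_truth(beta1 = c(R01 = 3))
  for (seed in 1:10) {
    scr <- simulate_screen(lib, des, tr, seed = seed)
    post <- scr$counts[, scr$samples$condition == "post_coculture"]
    pre <- scr$counts[, "pre_selection"]
    ratio <- (post + 0.5) / (pre + 0.5)
    fam <- tapply(ratio, lib$constructs$gene1, mean)
    expect_equal(names(which.max(fam)), "R01")
  }
})

test_that("sequencing counts are overdispersed yet conserve depth", {
  cells <- c(0, rep(100, 99))
  x0 <- sequence_counts(cells, depth = 1e4, nb_dispersion = 0, seed = 1)
  expect_equal(sum(x0), 1e4)
  expect_equal(x0[1], 0L)

  # variance/mean across constructs exceeds Poisson when dispersion > 0
  vm <- sapply(1:20, function(s) {
    x <- sequence_counts(cells[-1], depth = 1e5, nb_dispersion = 0.1, seed = s)
    var(as.numeric(x)) / mean(x)
  })
  expect_gt(mean(vm), 1)
  sums <- sapply(1:5, function(s) sum(sequence_counts(cells, 12345, 0.1, seed = s)))
  expect_true(all(sums == 12345))
})

test_that("simulate_screen is deterministic and emits the designed samples", {
  lib <- toy_library()
  des <- screen_design(et_ratios = c(0.5, 1, 2, 5), replicates = 2, screens = 2,
                       depth = 1e4)
  a <- simulate_screen(lib, des, seed = 99)
  b <- simulate_screen(lib, des, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  # 2 screens x 4 E:T x 2 replicates + pre-selection + plasmid = 18 columns
  expect_equal(ncol(a$counts), 18L)
  expect_equal(sum(a$samples$condition == "post_coculture"), 16L)
})

test_that("a null-truth screen gives per-construct fold changes centered at zero", {
  lib <- qc_library()
  des <- screen_design(et_ratios = c(0.5, 1, 2, 5), replicates = 2, screens = 2,
                       depth = 2e5, coverage = 500)
  scr <- simulate_screen(lib, des, seed = 17)
  nm <- cpm_log_normalize(scr)
  lfc <- log2fc(nm, select_samples(nm, condition = "post_coculture"), "pre_selection")
  z <- mean(lfc) / (sd(lfc) / sqrt(length(lfc)))
  expect_lt(abs(z), 4)
  expect_gt(mean(abs(lfc - mean(lfc)) < 4 * sd(lfc)), 0.99)
})

test_that("emitted FASTQ conserves read pairs and survives sequencing errors", {
  lib <- toy_library()
  counts <- stats::setNames(c(10L, 7L, 0L, 3L, 12L, 5L, 2L, 1L, 9L),
                            lib$constructs$construct_id)
  r1 <- withr::local_tempfile(fileext = "_R1.fastq.gz")
  r2 <- withr::local_tempfile(fileext = "_R2.fastq.gz")
  info <- emit_fastq(counts, lib, read_length = 30, error_rate = 0,
                     r1_path = r1, r2_path = r2, seed = 8)
  expect_equal(info$n_pairs, sum(counts))
  res <- count_fastq(r1, r2, lib, max_mismatch = 0)
  expect_identical(res$counts, counts)

  # read length must cover the spacer span
  expect_error(emit_fastq(counts, lib, read_length = 10, error_rate = 0,
                          r1_path = r1, r2_path = r2), "read_length")

  # at error rate 0.001 with 1-mismatch matching, nearly all pairs map
  big <- stats::setNames(rep(200L, 9), lib$constructs$construct_id)
  emit_fastq(big, lib, read_length = 30, error_rate = 0.001,
             r1_path = r1, r2_path = r2, seed = 9)
  res2 <- count_fastq(r1, r2, lib, max_mismatch = 1)
  expect_gte(res2$stats$mapped / res2$stats$total_pairs, 0.98)
})
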