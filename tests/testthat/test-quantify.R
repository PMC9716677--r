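test_that("guide index resolves exact, 1-mismatch and ambiguous spacers", {
  # hand-picked spacers: s1 and s2 differ at exactly two positions, so a
  # query matching each at distance 1 is ambiguous
  sp <- data.frame(
    position = c(1, 1, 1, 2, 2),
    spacer = c("AAAAAAAAAA", "AACCAAAAAA", "GGGGGGGGGG",
               "TTTTTTTTTT", "CCCCCCCCCC"))
  lib <- build_dual_library(c("A", "B"), c("C"), 1, 1, 1, 1, spacers = sp)
  idx <- build_guide_index(lib, max_mismatch = 1)
  layout <- cassette_layout(flank5 = "", linker = "", flank3 = "")

  g1 <- lib$guides[lib$guides$position == 1, ]
  exact <- match_read_pair("AAAAAAAAAA", "TTTTTTTTTT", idx, layout)
  expect_equal(exact$status, "mapped")
  expect_equal(exact$guide1_id, g1$guide_id[g1$target_gene == "A"])

  onemm <- match_read_pair("AAAAAAAAAT", "TTTTTTTTTT", idx, layout)
  expect_equal(onemm$status, "mapped")
  expect_equal(onemm$guide1_id, g1$guide_id[g1$target_gene == "A"])

  # "AACAAAAAAA" is Hamming-1 from both A's and B's spacers -> ambiguous
  ambig <- match_read_pair("AACAAAAAAA", "TTTTTTTTTT", idx, layout)
  expect_equal(ambig$status, "unmapped")

  # exact-only index rejects the 1-mismatch query
  idx0 <- build_guide_index(lib, max_mismatch = 0)
  expect_equal(match_read_pair("AAAAAAAAAT", "TTTTTTTTTT", idx0, layout)$status,
               "unmapped")
})

test_that("indexed matcher agrees with the brute-force Hamming oracle", {
  lib <- build_dual_library(c("A", "B", "C"), c("D", "E"), 2, 2, 2, 2, seed = 21)
  layout <- cassette_layout()
  L <- lib$metadata$spacer_length
  bases <- c("A", "C", "G", "T")

  set.seed(402)
  make_reads <- function(n) {
    cs <- lib$constructs[sample.int(nrow(lib$constructs), n, replace = TRUE), ]
    r1 <- paste0(layout$flank5, cs$spacer1, substr(layout$linker, 1, 4))
    r2 <- paste0(cs$spacer2, layout$flank3)
    # mutate spacer regions with 0-2 errors; some reads become pure junk
    k1 <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    k2 <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    for (i in seq_len(n)) {
      if (k1[i] > 0) for (p in sample.int(L, k1[i]))
        substr(r1[i], layout$r1_offset + p, layout$r1_offset + p) <- sample(bases, 1)
      if (k2[i] > 0) for (p in sample.int(L, k2[i]))
        substr(r2[i], p, p) <- sample(bases, 1)
    }
    junk <- sample.int(n, max(1, n %/% 20))
    r1[junk] <- vapply(junk, function(i) paste(sample(bases, nchar(r1[i]), TRUE),
                                               collapse = ""), character(1))
    list(r1 = r1, r2 = r2)
  }

  reads <- make_reads(300)
  for (mm in c(0, 1)) {
    idx <- build_guide_index(lib, max_mismatch = mm)
    fast <- match_read_pair(reads$r1, reads$r2, idx, layout)
    slow <- brute_force_match(reads$r1, reads$r2, lib, layout, mm)
    expect_identical(fast$status, slow$status)
    expect_identical(fast$construct_id, slow$construct_id)
  }
})

test_that("1-mismatch matching never maps fewer pairs than exact matching", {
  lib <- qc_library()
  counts <- stats::setNames(rep(30L, nrow(lib$constructs)),
                            lib$constructs$construct_id)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts, lib, read_length = 30, error_rate = 0.02,
             r1_path = r1, r2_path = r2, seed = 31)
  res0 <- count_fastq(r1, r2, lib, max_mismatch = 0)
  res1 <- count_fastq(r1, r2, lib, max_mismatch = 1)
  expect_gte(res1$stats$mapped, res0$stats$mapped)
  for (res in list(res0, res1)) {
    s <- res$stats
    expect_equal(s$mapped + s$recombinant + s$unmapped, s$total_pairs)
  }
})

test_that("recombinant pairs (guides never cloned together) are tallied, not counted", {
  lib <- toy_library()
  # drop one DKO construct from the library: its guide pair becomes recombinant
  dropped <- lib$constructs$construct_id[1]
  sub <- lib
  sub$constructs <- lib$constructs[-1, ]
  expect_true(validate_library(sub)$pass)

  counts_full <- stats::setNames(rep(5L, 9), lib$constructs$construct_id)
  r1 <- withr::local_tempfile(fileext = ".fastq")
  r2 <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(counts_full, lib, read_length = 30, error_rate = 0,
             r1_path = r1, r2_path = r2, seed = 41)
  res <- count_fastq(r1, r2, sub)
  expect_equal(res$stats$recombinant, 5L)
  expect_equal(res$stats$mapped, 40L)
  expect_false(dropped %in% names(which(res$counts > 0)))

  # a valid guide1 with an unknown slot-2 spacer is unmapped by definition
  idx <- build_guide_index(lib)
  layout <- cassette_layout()
  r1s <- paste0(layout$flank5, lib$constructs$spacer1[1], strrep("A", 10))
  expect_equal(match_read_pair(r1s, strrep("A", 30), idx, layout)$status, "unmapped")
})

test_that("count_fastq reproduces a simulated column and handles edge cases", {
  lib <- qc_library()
  scr <- simulate_screen(lib, screen_design(et_ratios = 2, replicates = 1,
                                            depth = 2e4), seed = 51)
  col <- scr$counts[, "pre_selection"]
  r1 <- withr::local_tempfile(fileext = ".fastq.gz")
  r2 <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(col, lib, read_length = 30, error_rate = 0, r1_path = r1,
             r2_path = r2, seed = 52)
  res <- count_fastq(r1, r2, lib)
  expect_identical(res$counts[names(col)], col)
  expect_equal(res$stats$total_pairs, sum(col))

  # at 500X coverage and adequate depth the library is essentially fully retained
  des <- screen_design(et_ratios = 2, replicates = 1, depth = 5e5, coverage = 500)
  scr2 <- simulate_screen(lib, des, seed = 53)
  expect_gte(library_retention(scr2$counts[, "pre_selection"]), 0.99)

  # empty FASTQ: all-zero column, zero totals
  e1 <- withr::local_tempfile(fileext = ".fastq"); file.create(e1)
  e2 <- withr::local_tempfile(fileext = ".fastq"); file.create(e2)
  res0 <- count_fastq(e1, e2, lib)
  expect_equal(res0$stats$total_pairs, 0L)
  expect_true(all(res0$counts == 0))

  # mismatched record counts are an error
  writeLines(c("@r1", strrep("A", 30), "+", strrep("I", 30)), e1)
  expect_error(count_fastq(e1, e2, lib), "records")
})
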