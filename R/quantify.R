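# Paired-guide quantification: extract the two spacers from a read pair at
# fixed layout offsets, resolve each against a per-position guide index
# (exact match, optionally one substitution), and count the construct. Pairs
# whose two guides are both known but never cloned together are recombinants
# (lentiviral template switching) and are tallied but excluded from the
# count matrix. Ambiguous 1-mismatch hits are discarded, never assigned.

one_mismatch_table <- function(spacers, guide_ids) {
  L <- nchar(spacers[1])
  bases <- c("A", "C", "G", "T")
  var_list <- vector("list", L)
  for (i in seq_len(L)) {
    cur <- substr(spacers, i, i)
    pre <- substr(spacers, 1L, i - 1L)
    suf <- substr(spacers, i + 1L, L)
    vs <- character(0)
    gs <- character(0)
    for (b in bases) {
      keep <- which(cur != b)
      if (!length(keep)) next
      vs <- c(vs, paste0(pre[keep], b, suf[keep]))
      gs <- c(gs, guide_ids[keep])
    }
    var_list[[i]] <- data.frame(variant = vs, guide = gs, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, var_list)
  # a variant reachable from >= 2 distinct guides is ambiguous at distance 1
  ng <- tapply(tab$guide, tab$variant, function(g) length(unique(g)))
  tab <- tab[!duplicated(tab$variant), ]
  tab$guide[ng[tab$variant] > 1] <- NA_character_
  tab
}

#' Build a paired-guide lookup index
#'
#' Per-position exact-match maps from spacer to guide id, plus (for
#' `max_mismatch = 1`) a Hamming-distance-1 neighborhood map in which
#' variants reachable from two or more guides are marked ambiguous. An exact
#' hit always wins over a 1-mismatch hit.
#'
#' @param lib A `dual_library` with a fixed spacer length.
#' @param max_mismatch 0 (exact only) or 1 (one substitution tolerated).
#' @return A `guide_index` object.
#' @export
build_guide_index <- function(lib, max_mismatch = 1) {
  stopifnot(max_mismatch %in% c(0, 1))
  g <- lib$guides
  if (length(unique(nchar(g$spacer))) != 1) fail("index requires a uniform spacer length")
  positions <- lapply(c(1L, 2L), function(p) {
    gp <- g[g$position == p, ]
    if (anyDuplicated(gp$spacer)) fail("duplicate spacer within position %d", p)
    nb <- if (max_mismatch == 1) one_mismatch_table(gp$spacer, gp$guide_id) else NULL
    list(spacers = gp$spacer, guide_ids = gp$guide_id, neighborhood = nb)
  })
  cs <- lib$constructs
  structure(list(positions = positions,
                 spacer_length = lib$metadata$spacer_length,
                 max_mismatch = max_mismatch,
                 pair_key = stats::setNames(cs$construct_id,
                                            paste(cs$guide1_id, cs$guide2_id))),
            class = "guide_index")
}

# vectorized: spacer strings -> guide ids (NA = unresolved or ambiguous)
resolve_spacers <- function(sp, pos_index, max_mismatch) {
  g <- pos_index$guide_ids[match(sp, pos_index$spacers)]
  if (max_mismatch >= 1) {
    miss <- which(is.na(g))
    if (length(miss)) {
      j <- match(sp[miss], pos_index$neighborhood$variant)
      g[miss] <- pos_index$neighborhood$guide[j]
    }
  }
  g
}

# vectorized pair matcher shared by match_read_pair() and count_fastq()
match_pairs_internal <- function(r1, r2, index, layout) {
  L <- index$spacer_length
  if (layout$r2_revcomp) r2 <- reverse_complement(r2)
  ok1 <- nchar(r1) >= layout$r1_offset + L
  ok2 <- nchar(r2) >= layout$r2_offset + L
  sp1 <- substr(r1, layout$r1_offset + 1L, layout$r1_offset + L)
  sp2 <- substr(r2, layout$r2_offset + 1L, layout$r2_offset + L)
  g1 <- rep(NA_character_, length(r1))
  g2 <- g1
  g1[ok1] <- resolve_spacers(sp1[ok1], index$positions[[1]], index$max_mismatch)
  g2[ok2] <- resolve_spacers(sp2[ok2], index$positions[[2]], index$max_mismatch)
  construct <- unname(index$pair_key[paste(g1, g2)])
  status <- ifelse(is.na(g1) | is.na(g2), "unmapped",
                   ifelse(is.na(construct), "recombinant", "mapped"))
  construct[status != "mapped"] <- NA_character_
  data.frame(status = status, construct_id = construct,
             guide1_id = ifelse(status == "unmapped", NA_character_, g1),
             guide2_id = ifelse(status == "unmapped", NA_character_, g2),
             stringsAsFactors = FALSE)
}

#' Match one read pair (or vectors of read pairs) to a construct
#'
#' Extracts the slot-1 spacer from R1 and the slot-2 spacer from R2 at the
#' layout offsets and resolves both against the index. Both guides known and
#' the pair in the library gives `mapped` with the construct id; both known
#' but not a library pair gives `recombinant`; anything else (short read,
#' unknown or ambiguous spacer) gives `unmapped`.
#'
#' @param r1,r2 Character vectors of read sequences (same length).
#' @param index A [build_guide_index()].
#' @param layout The [cassette_layout()] the reads follow.
#' @return Data frame with columns `status`, `construct_id`, `guide1_id`,
#'   `guide2_id`, one row per read pair.
#' @export
match_read_pair <- function(r1, r2, index, layout = cassette_layout()) {
  stopifnot(length(r1) == length(r2))
  match_pairs_internal(r1, r2, index, layout)
}

#' Count paired-guide constructs from paired FASTQ files
#'
#' Streams both mates, matches every pair with [match_read_pair()], and
#' returns the per-construct count column (zeros included for unseen
#' constructs) together with counting statistics satisfying
#' `mapped + recombinant + unmapped = total_pairs`.
#'
#' @param r1_path,r2_path FASTQ paths (gzip-transparent).
#' @param lib The `dual_library` to count against.
#' @param layout A [cassette_layout()].
#' @param max_mismatch 0 or 1 substitutions tolerated per spacer.
#' @param index Optional prebuilt [build_guide_index()] (must match
#'   `max_mismatch`).
#' @return A `counting_result` list: integer `counts` named by construct id,
#'   and `stats` (total_pairs, mapped, recombinant, unmapped).
#' @export
count_fastq <- function(r1_path, r2_path, lib, layout = cassette_layout(),
                        max_mismatch = 1, index = NULL) {
  for (p in c(r1_path, r2_path)) if (!file.exists(p)) fail("no such file: %s", p)
  if (is.null(index)) index <- build_guide_index(lib, max_mismatch = max_mismatch)
  read_fq <- function(p) {
    if (file.size(p) == 0) return(character(0))
    as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
  }
  r1 <- read_fq(r1_path)
  r2 <- read_fq(r2_path)
  if (length(r1) != length(r2))
    fail("R1 has %d records but R2 has %d", length(r1), length(r2))

  counts <- stats::setNames(integer(nrow(lib$constructs)), lib$constructs$construct_id)
  stats <- list(total_pairs = length(r1), mapped = 0L, recombinant = 0L, unmapped = 0L)
  if (length(r1)) {
    calls <- match_pairs_internal(r1, r2, index, layout)
    tab <- table(calls$construct_id[calls$status == "mapped"])
    counts[names(tab)] <- as.integer(tab)
    stats$mapped <- sum(calls$status == "mapped")
    stats$recombinant <- sum(calls$status == "recombinant")
    stats$unmapped <- sum(calls$status == "unmapped")
  }
  structure(list(counts = counts, stats = stats), class = "counting_result")
}

#' @export
print.counting_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf("counting_result: %d pairs (%d mapped, %d recombinant, %d unmapped), %d/%d constructs seen\n",
              s$total_pairs, s$mapped, s$recombinant, s$unmapped,
              sum(x$counts > 0), length(x$counts)))
  invisible(x)
}

#' Fraction of library constructs observed at least once
#'
#' Library retention, the NGS check that a transduced pool still represents
#' the cloned library.
#'
#' @param counts Integer count vector over all library constructs.
#' @return Fraction in [0, 1].
#' @export
library_retention <- function(counts) mean(counts > 0)
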