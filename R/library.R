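# Asymmetric dual-guide library construction: position 1 carries guides against
# candidate resistance genes, position 2 guides against tumor suppressors.
# Crossing the two slots yields double knockouts (DKO); non-targeting controls
# (NTC) in either slot yield single knockouts (SKO_POS1 / SKO_POS2) and
# double non-targeting controls (DNTC).

CONSTRUCT_CATEGORIES <- c("DKO", "SKO_POS1", "SKO_POS2", "DNTC")
NTC_LABEL <- "NTC"

#' Generate random spacer sequences for simulated libraries
#'
#' Draws random 20-mers (by default) subject to loose oligo-design constraints:
#' GC content within `gc_range` and no homopolymer run longer than
#' `max_homopolymer`. Generated spacers are for simulation only; real screens
#' supply their own spacer table to [build_dual_library()].
#'
#' @param n Number of distinct spacers required.
#' @param length Spacer length in nucleotides.
#' @param gc_range Allowed GC fraction, inclusive.
#' @param max_homopolymer Longest allowed single-base run.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Character vector of `n` unique spacers.
#' @export
generate_spacers <- function(n, length = 20, gc_range = c(0.4, 0.6),
                             max_homopolymer = 4, seed = NULL) {
  stopifnot(n >= 1, length >= 1, max_homopolymer >= 1)
  with_seed_(seed, {
    out <- character(0)
    tries <- 0L
    run_re <- sprintf("([ACGT])\\1{%d}", max_homopolymer)
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L) fail("could not generate %d spacers under the stated constraints", n)
      m <- matrix(sample(c("A", "C", "G", "T"), 2L * n * length, replace = TRUE),
                  ncol = length)
      cand <- apply(m, 1L, paste0, collapse = "")
      keep <- gc_fraction(cand) >= gc_range[1] & gc_fraction(cand) <= gc_range[2] &
        !grepl(run_re, cand, perl = TRUE)
      out <- unique(c(out, cand[keep]))
    }
    out[seq_len(n)]
  })
}

guide_tag <- function(gene, idx) paste0(gene, ".", idx)

make_guides <- function(genes, guides_per_gene, n_ntc, position, spacers) {
  gene_col <- c(rep(genes, each = guides_per_gene), rep(NTC_LABEL, n_ntc))
  idx_col <- c(rep(seq_len(guides_per_gene), times = length(genes)), seq_len(n_ntc))
  data.frame(
    guide_id = paste0("p", position, "_", guide_tag(gene_col, idx_col)),
    target_gene = gene_col,
    position = position,
    spacer = spacers,
    stringsAsFactors = FALSE
  )
}

canonical_guide_order <- function(guides) {
  guides[order(guides$position, guides$guide_id), , drop = FALSE]
}

#' Build an asymmetric dual-knockout library
#'
#' Constructs the full cross of position-1 gene guides with position-2 gene
#' guides (DKO), each targeting guide with the opposite slot's non-targeting
#' controls (SKO_POS1 / SKO_POS2), and all NTC x NTC combinations (DNTC).
#' The design is asymmetric: slot 1 holds the resistance-gene guides, slot 2
#' the tumor-suppressor guides, and no slot-swapped duplicates are created.
#'
#' @param pos1_genes,pos2_genes Character vectors of gene symbols for each
#'   slot; no duplicates, and the reserved label `"NTC"` is not allowed.
#' @param guides_per_pos1_gene,guides_per_pos2_gene Guides per targeted gene.
#' @param ntc_pos1,ntc_pos2 Number of non-targeting guides per slot. Control
#'   count matters downstream: SKO summaries and the control-based empirical
#'   FDR both gain resolution with more NTCs (see the methods vignette).
#' @param spacers Optional data.frame with columns `position` and `spacer`
#'   supplying spacer sequences in guide order (slot-1 guides first); when
#'   `NULL`, spacers are generated with [generate_spacers()] and the library
#'   metadata records `spacer_source = "generated"`.
#' @param spacer_length Spacer length when generating.
#' @param name Library name stored in metadata.
#' @param seed Seed for spacer generation.
#' @return A `dual_library` object: list with `guides`, `constructs` and
#'   `metadata` (see the library CSV columns in [write_library()]).
#' @examples
#' lib <- build_dual_library(c("Jak1", "Jak2"), c("Trp53", "Pten"),
#'                           guides_per_pos1_gene = 1, guides_per_pos2_gene = 1,
#'                           ntc_pos1 = 1, ntc_pos2 = 1, seed = 1)
#' table(lib$constructs$category)
#' @export
build_dual_library <- function(pos1_genes, pos2_genes,
                               guides_per_pos1_gene = 3, guides_per_pos2_gene = 3,
                               ntc_pos1 = 10, ntc_pos2 = 10,
                               spacers = NULL, spacer_length = 20,
                               name = "dual_ko_library", seed = NULL) {
  for (nm in c("pos1_genes", "pos2_genes")) {
    genes <- get(nm)
    if (length(genes) == 0) fail("%s must be non-empty", nm)
    dup <- unique(genes[duplicated(genes)])
    if (length(dup)) fail("duplicate gene(s) in %s: %s", nm, paste(dup, collapse = ", "))
    if (NTC_LABEL %in% genes) fail("'%s' is reserved for non-targeting controls", NTC_LABEL)
  }
  stopifnot(guides_per_pos1_gene >= 1, guides_per_pos2_gene >= 1,
            ntc_pos1 >= 1, ntc_pos2 >= 1)

  n1 <- length(pos1_genes) * guides_per_pos1_gene + ntc_pos1
  n2 <- length(pos2_genes) * guides_per_pos2_gene + ntc_pos2
  if (is.null(spacers)) {
    sp <- generate_spacers(n1 + n2, length = spacer_length, seed = seed)
    spacer_source <- "generated"
  } else {
    stopifnot(is.data.frame(spacers), all(c("position", "spacer") %in% names(spacers)))
    sp1 <- spacers$spacer[spacers$position == 1]
    sp2 <- spacers$spacer[spacers$position == 2]
    if (length(sp1) != n1 || length(sp2) != n2)
      fail("spacer table must supply %d position-1 and %d position-2 spacers", n1, n2)
    sp <- c(sp1, sp2)
    if (!all(is_nucleotide(sp))) fail("spacers contain non-ACGT characters")
    if (length(unique(nchar(sp))) != 1) fail("spacers must share a fixed length")
    spacer_length <- nchar(sp[1])
    spacer_source <- "supplied"
  }
  if (anyDuplicated(sp[seq_len(n1)]) || anyDuplicated(sp[n1 + seq_len(n2)]))
    fail("spacer collision within a position")

  g1 <- make_guides(pos1_genes, guides_per_pos1_gene, ntc_pos1, 1L, sp[seq_len(n1)])
  g2 <- make_guides(pos2_genes, guides_per_pos2_gene, ntc_pos2, 2L, sp[n1 + seq_len(n2)])

  t1 <- g1$target_gene != NTC_LABEL   # targeting mask, slot 1
  t2 <- g2$target_gene != NTC_LABEL

  cross <- function(i_rows, j_rows, category) {
    if (!length(i_rows) || !length(j_rows)) return(NULL)
    i <- rep(i_rows, each = length(j_rows))
    j <- rep(j_rows, times = length(i_rows))
    data.frame(
      construct_id = paste0(sub("^p1_", "", g1$guide_id[i]), "__",
                            sub("^p2_", "", g2$guide_id[j])),
      guide1_id = g1$guide_id[i], gene1 = g1$target_gene[i], spacer1 = g1$spacer[i],
      guide2_id = g2$guide_id[j], gene2 = g2$target_gene[j], spacer2 = g2$spacer[j],
      category = category,
      stringsAsFactors = FALSE
    )
  }

  constructs <- rbind(
    cross(which(t1), which(t2), "DKO"),
    cross(which(t1), which(!t2), "SKO_POS1"),
    cross(which(!t1), which(t2), "SKO_POS2"),
    cross(which(!t1), which(!t2), "DNTC")
  )
  rownames(constructs) <- NULL

  lib <- structure(
    list(
      guides = canonical_guide_order(rbind(g1, g2)),
      constructs = constructs,
      metadata = list(name = name, spacer_length = spacer_length,
                      spacer_source = spacer_source)
    ),
    class = "dual_library"
  )
  rownames(lib$guides) <- NULL
  lib
}

#' @export
print.dual_library <- function(x, ...) {
  cen <- table(factor(x$constructs$category, levels = CONSTRUCT_CATEGORIES))
  cat(sprintf("dual_library '%s': %d guides, %d constructs (spacer length %d, %s spacers)\n",
              x$metadata$name, nrow(x$guides), nrow(x$constructs),
              x$metadata$spacer_length, x$metadata$spacer_source))
  print(cen)
  invisible(x)
}

expected_category <- function(gene1, gene2) {
  ifelse(gene1 != NTC_LABEL & gene2 != NTC_LABEL, "DKO",
    ifelse(gene1 != NTC_LABEL, "SKO_POS1",
      ifelse(gene2 != NTC_LABEL, "SKO_POS2", "DNTC")))
}

#' Validate a dual-guide library
#'
#' Report-only check of every library invariant: spacer alphabet and fixed
#' length, uniqueness of (position, spacer) and of construct ids and guide
#' pairs, slot-consistent guide references, and category labels consistent
#' with the NTC content of each construct.
#'
#' @param lib A `dual_library` (or a structurally compatible list).
#' @return List with elements `pass` (logical) and `violations`
#'   (character vector, empty when `pass` is `TRUE`).
#' @export
validate_library <- function(lib) {
  v <- character(0)
  g <- lib$guides
  cs <- lib$constructs

  if (!all(is_nucleotide(g$spacer))) v <- c(v, "guide spacers contain non-ACGT characters")
  if (length(unique(nchar(g$spacer))) > 1) v <- c(v, "spacer length is not fixed across guides")
  key <- paste(g$position, g$spacer)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    v <- c(v, sprintf("duplicate (position, spacer): %s", paste(dup, collapse = "; ")))
  }
  if (anyDuplicated(g$guide_id)) v <- c(v, "duplicate guide_id")
  if (anyDuplicated(cs$construct_id)) v <- c(v, "duplicate construct_id")
  if (anyDuplicated(paste(cs$guide1_id, cs$guide2_id)))
    v <- c(v, "duplicate (guide1, guide2) pair")

  g1 <- g[g$position == 1L, ]
  g2 <- g[g$position == 2L, ]
  bad1 <- !(cs$guide1_id %in% g1$guide_id)
  bad2 <- !(cs$guide2_id %in% g2$guide_id)
  if (any(bad1)) v <- c(v, sprintf("%d construct(s) reference unknown/position-2 guides in slot 1", sum(bad1)))
  if (any(bad2)) v <- c(v, sprintf("%d construct(s) reference unknown/position-1 guides in slot 2", sum(bad2)))

  exp_cat <- expected_category(cs$gene1, cs$gene2)
  mis <- cs$category != exp_cat
  if (any(mis))
    v <- c(v, sprintf("category inconsistent with guide content for: %s",
                      paste(utils::head(cs$construct_id[mis], 5), collapse = ", ")))
  if (!all(cs$category %in% CONSTRUCT_CATEGORIES)) v <- c(v, "unknown category label")
  if (sum(table(factor(cs$category, levels = CONSTRUCT_CATEGORIES))) != nrow(cs))
    v <- c(v, "category census does not sum to construct total")

  list(pass = length(v) == 0L, violations = v)
}

LIBRARY_CSV_COLUMNS <- c("construct_id", "guide1_id", "gene1", "spacer1",
                         "guide2_id", "gene2", "spacer2", "category")

#' Write / read a library as CSV
#'
#' The CSV holds one row per construct with columns
#' `construct_id, guide1_id, gene1, spacer1, guide2_id, gene2, spacer2,
#' category`, preceded by a single `#`-prefixed metadata line. The round trip
#' `read_library(write_library(lib, path))` reproduces `lib` exactly.
#'
#' @param lib A valid `dual_library`.
#' @param path Output CSV path.
#' @return `write_library` returns `path` invisibly; `read_library` returns a
#'   `dual_library`.
#' @export
write_library <- function(lib, path) {
  chk <- validate_library(lib)
  if (!chk$pass) fail("refusing to write invalid library: %s", chk$violations[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dual_library name=%s spacer_length=%d spacer_source=%s",
                     lib$metadata$name, lib$metadata$spacer_length,
                     lib$metadata$spacer_source), con)
  utils::write.csv(lib$constructs[, LIBRARY_CSV_COLUMNS], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) fail("no such file: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !any(nzchar(lines))) fail("empty library file: %s", path)
  meta <- list(name = "dual_ko_library", spacer_length = NA_integer_,
               spacer_source = "supplied")
  if (startsWith(lines[1], "#")) {
    for (kv in regmatches(lines[1], gregexpr("[a-z_]+=[^ ]+", lines[1]))[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- p[2]
    }
    meta$spacer_length <- as.integer(meta$spacer_length)
  }
  cs <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(LIBRARY_CSV_COLUMNS, names(cs))
  if (length(missing_cols))
    fail("library CSV is missing column(s): %s", paste(missing_cols, collapse = ", "))
  bad <- which(apply(is.na(cs[LIBRARY_CSV_COLUMNS]) | cs[LIBRARY_CSV_COLUMNS] == "", 1L, any))
  if (length(bad)) fail("malformed library row(s): %s", paste(bad, collapse = ", "))
  cs <- cs[, LIBRARY_CSV_COLUMNS]

  guides <- unique(rbind(
    data.frame(guide_id = cs$guide1_id, target_gene = cs$gene1, position = 1L,
               spacer = cs$spacer1, stringsAsFactors = FALSE),
    data.frame(guide_id = cs$guide2_id, target_gene = cs$gene2, position = 2L,
               spacer = cs$spacer2, stringsAsFactors = FALSE)
  ))
  guides <- canonical_guide_order(guides)
  rownames(guides) <- NULL
  if (is.na(meta$spacer_length)) meta$spacer_length <- nchar(guides$spacer[1])

  lib <- structure(list(guides = guides, constructs = cs,
                        metadata = list(name = meta$name,
                                        spacer_length = meta$spacer_length,
                                        spacer_source = meta$spacer_source)),
                   class = "dual_library")
  chk <- validate_library(lib)
  if (!chk$pass) fail("library read from %s is invalid: %s", path, chk$violations[1])
  lib
}

#' Dual-cassette layout
#'
#' Describes the fixed sequence context around the two spacers in the vector
#' cassette: `flank5 + spacer1 + linker + spacer2 + flank3`. Read 1 covers the
#' slot-1 spacer starting at `r1_offset = nchar(flank5)`; read 2 covers the
#' slot-2 spacer at `r2_offset` (default 0, i.e. the R2 sequencing primer sits
#' at the end of the linker and R2 reads the slot-2 spacer directly; set
#' `r2_revcomp = TRUE` when R2 reads the opposite strand).
#'
#' @param flank5,linker,flank3 Fixed cassette sequences (may be empty strings).
#' @param r2_offset Offset of the slot-2 spacer within read 2.
#' @param r2_revcomp Should read 2 be reverse-complemented before slot-2 lookup?
#' @return A `cassette_layout` list.
#' @export
cassette_layout <- function(flank5 = "ACCG",
                            linker = "GTTTAAGAGCTAAGCTGGAAACAGCATAGCAAG",
                            flank3 = "TTTTTTT",
                            r2_offset = 0L, r2_revcomp = FALSE) {
  seqs <- c(flank5, linker, flank3)
  if (!all(is_nucleotide(seqs[nzchar(seqs)]))) fail("layout flanks must be A/C/G/T strings")
  structure(list(flank5 = flank5, linker = linker, flank3 = flank3,
                 r1_offset = nchar(flank5), r2_offset = as.integer(r2_offset),
                 r2_revcomp = isTRUE(r2_revcomp)),
            class = "cassette_layout")
}

cassette_sequences <- function(lib, layout) {
  paste0(layout$flank5, lib$constructs$spacer1, layout$linker,
         lib$constructs$spacer2, layout$flank3)
}

#' Write cassette reference sequences as FASTA
#'
#' One record per construct, `flank5 + spacer1 + linker + spacer2 + flank3`,
#' with the construct id as record id. Used as the alignment/simulation
#' reference for the paired-guide readout.
#'
#' @param lib A `dual_library`.
#' @param layout A [cassette_layout()].
#' @param path Optional FASTA path; when given the set is written there.
#' @return A [Biostrings::DNAStringSet] named by construct id (invisibly when
#'   `path` is given).
#' @export
cassette_fasta <- function(lib, layout = cassette_layout(), path = NULL) {
  seqs <- Biostrings::DNAStringSet(cassette_sequences(lib, layout))
  names(seqs) <- lib$constructs$construct_id
  if (!is.null(path)) {
    Biostrings::writeXStringSet(seqs, path)
    return(invisible(seqs))
  }
  seqs
}
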