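# Generative model of the double-knockout co-culture screen. The chain is:
# plasmid pool (log-normal abundance) -> low-MOI transduction bottleneck
# (Poisson single-integration, multinomial allocation) -> T cell selection
# whose strength grows with the effector:target (E:T) ratio -> overdispersed
# sequencing (gamma-multinomial, i.e. negative binomial with fixed depth).
# Fitness is additive on the log2 scale: a construct carrying genes (A, B)
# has log2 survival effect beta1[A] + beta2[B] + gamma[A, B], so the
# "observed = expected" null of the interaction module is exact when gamma = 0.

#' Screen design parameters
#'
#' @param moi Mean viral integrations per cell; kept low (< 0.2) so that most
#'   infected cells carry a single construct.
#' @param coverage Transduced cells per library construct (e.g. 500 for a
#'   500X screen).
#' @param et_ratios Effector:target ratios at which selection is applied.
#' @param replicates Technical replicates: independent sequencing draws per
#'   selected pool (and a single pre-selection pool sequenced once).
#' @param screens Number of independent selection screens.
#' @param depth Sequencing reads per sample.
#' @param n_cells Optional explicit number of transduced cells; by default
#'   derived as `coverage * n_constructs`.
#' @return A `screen_design` list.
#' @export
screen_design <- function(moi = 0.1, coverage = 500, et_ratios = c(2, 5),
                          replicates = 3, screens = 1, depth = 5e6,
                          n_cells = NULL) {
  stopifnot(moi > 0, coverage > 0, all(et_ratios >= 0), replicates >= 1,
            screens >= 1, depth > 0)
  structure(list(moi = moi, coverage = coverage, et_ratios = et_ratios,
                 replicates = as.integer(replicates), screens = as.integer(screens),
                 depth = depth, n_cells = n_cells),
            class = "screen_design")
}

#' Ground-truth fitness effects for simulation
#'
#' Per-gene log2 survival effects under T cell pressure (`beta1` for slot-1
#' resistance genes, `beta2` for slot-2 tumor suppressors) and per-pair log2
#' interaction terms `gamma`. Positive `gamma` means the double knockout
#' survives better than the additive expectation from its two single
#' knockouts (an additive interaction in the screen's usage); negative
#' `gamma` a subtractive one. Non-targeting controls always have effect 0.
#'
#' @param beta1,beta2 Named numeric vectors of per-gene log2 effects; genes
#'   not listed default to 0.
#' @param interactions Data frame with columns `gene1`, `gene2`, `gamma`
#'   (one row per interacting pair), or `NULL` for no interactions.
#' @return A `fitness_truth` list.
#' @export
fitness_truth <- function(beta1 = numeric(0), beta2 = numeric(0),
                          interactions = NULL) {
  chk <- function(x, nm) {
    if (length(x)) stopifnot(!is.null(names(x)), all(is.finite(x)))
    if (NTC_LABEL %in% names(x) && any(x[names(x) == NTC_LABEL] != 0)) {
      warn("%s effect for NTC is forced to 0", nm)
      x[names(x) == NTC_LABEL] <- 0
    }
    x
  }
  beta1 <- chk(beta1, "beta1")
  beta2 <- chk(beta2, "beta2")
  if (is.null(interactions)) {
    interactions <- data.frame(gene1 = character(0), gene2 = character(0),
                               gamma = numeric(0))
  }
  stopifnot(all(c("gene1", "gene2", "gamma") %in% names(interactions)),
            all(is.finite(interactions$gamma)))
  if (any(interactions$gene1 == NTC_LABEL | interactions$gene2 == NTC_LABEL))
    fail("interaction terms cannot involve NTC")
  structure(list(beta1 = beta1, beta2 = beta2, interactions = interactions),
            class = "fitness_truth")
}

#' Noise model for the simulated screen
#'
#' @param plasmid_sigma Standard deviation of log plasmid abundance
#'   (log-normal construct representation in the cloned pool).
#' @param nb_dispersion Negative-binomial overdispersion of sequencing counts
#'   (variance = mu + dispersion * mu^2), implemented as a gamma-multinomial
#'   mixture so each sample sums exactly to its depth.
#' @param baseline_kill Function E:T ratio -> kill fraction in [0, 1) for a
#'   neutral construct. Default rises from 0.1 at E:T 0.1 to 0.9 at E:T 5
#'   (linear in log E:T, clamped).
#' @param selection_scale Function E:T -> non-negative, non-decreasing
#'   multiplier s(ET) applied to the log2 fitness terms; default
#'   `ET / (1 + ET)`, saturating at strong selection.
#' @return A `noise_model` list.
#' @export
noise_model <- function(plasmid_sigma = 0.5, nb_dispersion = 0.05,
                        baseline_kill = NULL, selection_scale = NULL) {
  stopifnot(plasmid_sigma >= 0, nb_dispersion >= 0)
  if (is.null(baseline_kill)) {
    baseline_kill <- function(et) {
      pmin(0.9, pmax(0.1, 0.1 + 0.8 * (log(pmax(et, 1e-9)) - log(0.1)) / (log(5) - log(0.1))))
    }
  }
  if (is.null(selection_scale)) selection_scale <- function(et) et / (1 + et)
  grid <- c(0.1, 0.5, 1, 2, 5)
  bk <- baseline_kill(grid)
  ss <- selection_scale(grid)
  if (any(bk < 0 | bk >= 1)) fail("baseline_kill must map into [0, 1)")
  if (any(ss < 0) || any(diff(ss) < 0)) fail("selection_scale must be non-negative and non-decreasing")
  structure(list(plasmid_sigma = plasmid_sigma, nb_dispersion = nb_dispersion,
                 baseline_kill = baseline_kill, selection_scale = selection_scale),
            class = "noise_model")
}

#' Sample plasmid-pool construct abundances
#'
#' Log-normal relative abundances: with `sigma = 0` every construct gets
#' exactly `1/N`; otherwise log abundances have standard deviation ~ `sigma`.
#'
#' @param lib A `dual_library`, or a single integer number of constructs.
#' @param sigma Log-scale dispersion.
#' @param seed Optional seed.
#' @return Named numeric vector summing to 1.
#' @export
sample_plasmid_abundance <- function(lib, sigma = 0.5, seed = NULL) {
  stopifnot(sigma >= 0)
  n <- if (inherits(lib, "dual_library")) nrow(lib$constructs) else as.integer(lib)
  ids <- if (inherits(lib, "dual_library")) lib$constructs$construct_id else NULL
  ab <- with_seed_(seed, {
    if (sigma == 0) rep(1 / n, n) else {
      x <- stats::rlnorm(n, meanlog = 0, sdlog = sigma)
      x / sum(x)
    }
  })
  names(ab) <- ids
  ab
}

#' Simulate the low-MOI transduction bottleneck
#'
#' With integrations per cell ~ Poisson(moi), the fraction of infected cells
#' carrying exactly one construct is `moi * exp(-moi) / (1 - exp(-moi))`.
#' Multiply-infected cells are discarded (at MOI < 0.2 they are < 10% of
#' infected cells); single-integration cells are allocated multinomially by
#' plasmid abundance.
#'
#' @param abundance Normalized abundance vector (sums to 1).
#' @param design A [screen_design()].
#' @param seed Optional seed.
#' @return Integer vector of pre-selection cells per construct.
#' @export
simulate_transduction <- function(abundance, design, seed = NULL) {
  stopifnot(abs(sum(abundance) - 1) < 1e-6, all(abundance >= 0))
  n <- length(abundance)
  n_cells <- design$n_cells %||% (design$coverage * n)
  if (!is.null(design$n_cells) && design$coverage * n > design$n_cells)
    warn("requested coverage (%gX over %d constructs) exceeds n_cells = %g",
         design$coverage, n, design$n_cells)
  single_frac <- design$moi * exp(-design$moi) / (1 - exp(-design$moi))
  n_single <- round(n_cells * single_frac)
  cells <- with_seed_(seed, as.integer(stats::rmultinom(1, n_single, abundance)))
  names(cells) <- names(abundance)
  cells
}

# log2 fitness effect per construct under the truth (beta1 + beta2 + gamma)
construct_effects <- function(lib, truth) {
  cs <- lib$constructs
  b1 <- ifelse(cs$gene1 %in% names(truth$beta1), truth$beta1[cs$gene1], 0)
  b2 <- ifelse(cs$gene2 %in% names(truth$beta2), truth$beta2[cs$gene2], 0)
  eff <- unname(b1 + b2)
  if (nrow(truth$interactions)) {
    key <- paste(cs$gene1, cs$gene2, sep = "\r")
    ikey <- paste(truth$interactions$gene1, truth$interactions$gene2, sep = "\r")
    m <- match(key, ikey)
    eff <- eff + ifelse(is.na(m), 0, truth$interactions$gamma[m])
  }
  eff
}

# per-cell survival probability for every construct at a given E:T ratio;
# values above 1 are clipped (count returned via attribute)
survival_probs <- function(lib, truth, noise, et_ratio) {
  s <- noise$selection_scale(et_ratio)
  bk <- noise$baseline_kill(et_ratio)
  p <- (1 - bk) * 2^(s * construct_effects(lib, truth))
  clipped <- sum(p > 1)
  structure(pmin(p, 1), clipped = clipped)
}

#' Simulate T cell selection at one E:T ratio
#'
#' Each cell carrying construct c (genes A, B) survives co-culture with
#' probability `min(1, (1 - baseline_kill(ET)) * 2^(s(ET) * (beta1_A +
#' beta2_B + gamma_AB)))`; survivors are drawn binomially per construct.
#' Probabilities exceeding 1 are clipped and the clip count reported via the
#' `"clipped"` attribute (strong resistance effects make this biologically
#' plausible).
#'
#' @param cell_counts Integer pre-selection cells per construct.
#' @param lib The `dual_library` the counts are indexed by.
#' @param truth A [fitness_truth()].
#' @param noise A [noise_model()].
#' @param et_ratio Effector:target ratio of this co-culture.
#' @param seed Optional seed.
#' @return Integer vector of post-selection cells, with attribute `clipped`.
#' @export
simulate_t_cell_selection <- function(cell_counts, lib, truth, noise, et_ratio,
                                      seed = NULL) {
  stopifnot(length(cell_counts) == nrow(lib$constructs), all(cell_counts >= 0))
  p <- survival_probs(lib, truth, noise, et_ratio)
  post <- with_seed_(seed, stats::rbinom(length(cell_counts), cell_counts, as.numeric(p)))
  names(post) <- names(cell_counts)
  structure(post, clipped = attr(p, "clipped"))
}

#' Simulate sequencing read counts
#'
#' Negative-binomially overdispersed counts around `depth * relative
#' abundance`, drawn as a gamma-multinomial mixture so the column sums to
#' `depth` exactly; with `nb_dispersion = 0` this reduces to a plain
#' multinomial. Constructs with zero input abundance always get zero reads.
#'
#' @param cell_counts Cell counts (or any non-negative abundance vector).
#' @param depth Total reads for the sample.
#' @param nb_dispersion Overdispersion (variance = mu + disp * mu^2).
#' @param seed Optional seed.
#' @return Integer read-count vector summing to `depth`.
#' @export
sequence_counts <- function(cell_counts, depth, nb_dispersion = 0.05, seed = NULL) {
  stopifnot(depth > 0, all(cell_counts >= 0), sum(cell_counts) > 0)
  prob <- cell_counts / sum(cell_counts)
  with_seed_(seed, {
    if (nb_dispersion > 0) {
      shape <- 1 / nb_dispersion
      g <- stats::rgamma(length(prob), shape = shape, rate = shape) * prob
      prob <- g / sum(g)
    }
    counts <- as.integer(stats::rmultinom(1, depth, prob))
    names(counts) <- names(cell_counts)
    counts
  })
}

#' Simulate a full screen into a count matrix
#'
#' Runs the whole generative chain from one seeded RNG stream: one plasmid
#' sample, one shared transduction giving one pre-selection sample, then an
#' independent selection per (screen, E:T ratio) with `replicates` technical
#' sequencing replicates each. For a design with S screens, E ratios and R
#' replicates the result has `S * E * R + 2` sample columns.
#'
#' @param lib A `dual_library`.
#' @param design A [screen_design()].
#' @param truth A [fitness_truth()]; default: no effects (null screen).
#' @param noise A [noise_model()].
#' @param seed Integer seed; the full output is reproducible given it.
#' @return A `screen_counts` object: list with integer matrix `counts`
#'   (constructs x samples), data.frame `samples` (sample_id, condition,
#'   et_ratio, replicate, screen), the `truth` used, the `design`, and the
#'   total number of clipped survival probabilities in `clipped`.
#' @export
simulate_screen <- function(lib, design = screen_design(),
                            truth = fitness_truth(), noise = noise_model(),
                            seed = NULL) {
  n <- nrow(lib$constructs)
  with_seed_(seed, {
    ab <- sample_plasmid_abundance(lib, sigma = noise$plasmid_sigma)
    plasmid <- sequence_counts(ab * 1e9, design$depth, noise$nb_dispersion)
    pre_cells <- simulate_transduction(ab, design)
    pre <- sequence_counts(pre_cells, design$depth, noise$nb_dispersion)

    cols <- list(plasmid = plasmid, pre_selection = pre)
    meta <- data.frame(sample_id = c("plasmid", "pre_selection"),
                       condition = c("plasmid", "pre_selection"),
                       et_ratio = NA_real_, replicate = NA_integer_,
                       screen = NA_integer_, stringsAsFactors = FALSE)
    clipped_total <- 0L
    for (sc in seq_len(design$screens)) {
      for (et in design$et_ratios) {
        post_cells <- simulate_t_cell_selection(pre_cells, lib, truth, noise, et)
        clipped_total <- clipped_total + attr(post_cells, "clipped")
        for (r in seq_len(design$replicates)) {
          sid <- sprintf("post_s%d_et%g_r%d", sc, et, r)
          cols[[sid]] <- sequence_counts(post_cells, design$depth, noise$nb_dispersion)
          meta <- rbind(meta, data.frame(sample_id = sid, condition = "post_coculture",
                                         et_ratio = et, replicate = r, screen = sc,
                                         stringsAsFactors = FALSE))
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- lib$constructs$construct_id
    structure(list(counts = counts, samples = meta, truth = truth,
                   design = design, clipped = clipped_total, seed = seed),
              class = "screen_counts")
  })
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d constructs x %d samples (%d post-co-culture)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$condition == "post_coculture")))
  if (x$clipped > 0)
    cat(sprintf("  note: %d survival probabilities clipped at 1\n", x$clipped))
  invisible(x)
}

#' Emit paired FASTQ reads for one count column
#'
#' Writes `counts[c]` read pairs per construct: R1 covers the slot-1 spacer at
#' the layout's `r1_offset`, R2 covers the slot-2 spacer at `r2_offset`.
#' Substitution errors are injected independently per base at `error_rate`.
#' Reads shorter than the cassette are padded with `A`.
#'
#' @param counts Integer read pairs per construct (aligned to `lib`).
#' @param lib A `dual_library`.
#' @param layout A [cassette_layout()].
#' @param read_length Read length; must cover offset + spacer length.
#' @param error_rate Per-base substitution probability.
#' @param r1_path,r2_path Output FASTQ paths (gzip when ending in `.gz`).
#' @param seed Optional seed.
#' @return Invisible list with the paths and the number of read pairs.
#' @export
emit_fastq <- function(counts, lib, layout = cassette_layout(), read_length = 30,
                       error_rate = 0, r1_path, r2_path, seed = NULL) {
  L <- lib$metadata$spacer_length
  if (read_length < layout$r1_offset + L || read_length < layout$r2_offset + L)
    fail("read_length %d does not cover offset + spacer length", read_length)
  stopifnot(length(counts) == nrow(lib$constructs), all(counts >= 0),
            error_rate >= 0, error_rate < 1)

  pad <- function(x) {
    short <- nchar(x) < read_length
    x[short] <- paste0(x[short], strrep("A", read_length - nchar(x[short])))
    substr(x, 1L, read_length)
  }
  cass <- cassette_sequences(lib, layout)
  r1_t <- pad(cass)
  # R2 begins r2_offset bases before the slot-2 spacer, i.e. inside the linker
  r2_prefix <- if (layout$r2_offset > 0) {
    lk <- layout$linker
    if (nchar(lk) < layout$r2_offset)
      lk <- paste0(strrep("A", layout$r2_offset - nchar(lk)), lk)
    substr(lk, nchar(lk) - layout$r2_offset + 1L, nchar(lk))
  } else ""
  r2_t <- pad(paste0(r2_prefix, lib$constructs$spacer2, layout$flank3))
  if (layout$r2_revcomp) r2_t <- reverse_complement(r2_t)

  with_seed_(seed, {
    idx <- rep(seq_along(counts), counts)
    if (length(idx)) idx <- sample(idx)  # interleave constructs as on a flow cell
    r1 <- r1_t[idx]
    r2 <- r2_t[idx]
    if (error_rate > 0 && length(idx)) {
      mutate <- function(reads) {
        nerr <- stats::rbinom(length(reads), read_length, error_rate)
        for (i in which(nerr > 0)) {
          pos <- sample.int(read_length, nerr[i])
          for (p in pos) {
            cur <- substr(reads[i], p, p)
            substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
        reads
      }
      r1 <- mutate(r1)
      r2 <- mutate(r2)
    }
    ids <- sprintf("read%08d", seq_along(idx))
    qual <- Biostrings::BStringSet(rep(strrep("I", read_length), length(idx)))
    for (side in list(list(r1, r1_path), list(r2, r2_path))) {
      x <- Biostrings::DNAStringSet(side[[1]])
      names(x) <- ids
      Biostrings::writeXStringSet(x, side[[2]], format = "fastq", qualities = qual,
                                  compress = endsWith(side[[2]], ".gz"))
    }
    invisible(list(r1_path = r1_path, r2_path = r2_path, n_pairs = length(idx)))
  })
}
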