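# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Wrapper around [withr::with_seed()] that is a no-op when `seed` is `NULL`
#' (the code then draws from the current RNG stream). All stochastic
#' operations in the package funnel through this, so every simulation is a
#' pure function of its inputs and its seed.
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed derivation; keeps derived seeds inside 32-bit range.
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483629)
}

# stop() with sprintf-style formatting and no call in the message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_nucleotide <- function(x) {
  vapply(x, function(s) !grepl("[^ACGT]", s), logical(1), USE.NAMES = FALSE)
}

# fraction of G/C characters in each string
gc_fraction <- function(x) {
  n <- nchar(x)
  ifelse(n == 0, 0, nchar(gsub("[AT]", "", x)) / pmax(n, 1L))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
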