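# Low-level sequence utilities shared across modules.

# Integer codes used throughout: gap = 0, A=1, C=2, G=3, T=4, N=5.
.CHAR_LEVELS <- c("-", "A", "C", "G", "T", "N")

#' Universal bacterial 16S primers delimiting the simulated amplicon
#'
#' The forward primer 27F and reverse primer 1492R bracket a ~1450 bp
#' fragment of the 16S rRNA gene. Synthetic reference amplicons begin with
#' the 27F site and end with the reverse complement of the 1492R site.
#' @format Character scalars.
#' @name primers
NULL

#' @rdname primers
#' @export
PRIMER_27F <- "AGAGTTTGATCCTGGCTCAG"

#' @rdname primers
#' @export
PRIMER_1492R <- "GGTTACCTTGTTACGACTT"

seq_to_codes <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], .CHAR_LEVELS) - 1L
  if (anyNA(x)) stop("sequence contains characters outside {A,C,G,T,N,-}")
  x
}

codes_to_seq <- function(x) paste(.CHAR_LEVELS[x + 1L], collapse = "")

#' Reverse complement of a nucleotide string
#'
#' Gaps and Ns are preserved ('N' complements to 'N').
#' @param s character scalar over \{A,C,G,T,N,-\}.
#' @return character scalar.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# All overlapping k-mer ids (base-4 integers) of a sequence; windows touching
# an N or gap are dropped. Returned in sequence order, duplicates kept.
kmer_ids <- function(s, k) {
  x <- seq_to_codes(s)
  v <- ifelse(x >= 1L & x <= 4L, x - 1L, NA_integer_)
  n <- length(v)
  if (n < k) return(integer(0))
  win <- embed(v, k)[, k:1, drop = FALSE]
  ids <- as.integer(win %*% 4^((k - 1):0))
  ids[!is.na(ids)]
}

# Run a block of code under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a master seed, kept inside the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 9973) %% 2147483647
}

# Substitute a fraction of the positions in `positions` (indices into the
# code vector) with a different random base. Expects RNG already seeded.
mutate_codes <- function(codes, frac, positions) {
  n_mut <- round(frac * length(positions))
  if (n_mut == 0) return(codes)
  at <- sample(positions, n_mut)
  for (i in at) {
    codes[i] <- sample(setdiff(1:4, codes[i]), 1)
  }
  codes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
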