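# Read preprocessing: quality masking, pair assembly, reference-guided
# alignment, gap-column trimming and length filtering.

#' Mask low-quality bases
#'
#' Replaces every base whose Phred quality is below `q_min` with `N`.
#' The published rule is stated as "Q >= 15 converted to N", which would
#' erase all usable data; the implemented default masks bases *below* Q15.
#' Set `literal = TRUE` to apply the printed reading for auditability.
#'
#' @param bases nucleotide string.
#' @param quals integer Phred scores, one per base.
#' @param q_min quality threshold (default 15).
#' @param literal mask bases with quality `>= q_min` instead.
#' @return masked nucleotide string of the same length.
#' @export
mask_low_quality <- function(bases, quals, q_min = 15, literal = FALSE) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  if (length(ch) != length(quals))
    stop("bases and qualities differ in length (", length(ch), " vs ",
         length(quals), ")")
  bad <- if (literal) quals >= q_min else quals < q_min
  ch[bad] <- "N"
  paste(ch, collapse = "")
}

#' Assemble a read pair when the two reads overlap
#'
#' Searches for the best suffix(fwd)/prefix(revcomp(rev)) overlap of at
#' least `min_overlap` bases and at least `min_identity` matching. If found,
#' returns the assembled contig, resolving disagreements in favour of the
#' higher-quality base; otherwise flags the pair for gapped concatenation.
#'
#' @param fwd,rev reads (`rev` in reverse-complement orientation, as read
#'   off the sequencer).
#' @param fwd_qual,rev_qual optional per-base Phred scores.
#' @param min_overlap minimum acceptable overlap (nt).
#' @param min_identity minimum fraction of matching bases in the overlap.
#' @return list with `assembled` (logical); if `TRUE` also `seq`, `qual` and
#'   `overlap_len`; if `FALSE` the inputs are passed through for
#'   concatenation.
#' @export
merge_pair <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                       min_overlap = 30, min_identity = 0.90) {
  if (!nzchar(fwd) || !nzchar(rev)) stop("both reads must be non-empty")
  fc <- strsplit(fwd, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(rev), "", fixed = TRUE)[[1]]
  fq <- fwd_qual %||% rep(30L, length(fc))
  rq <- rev(rev_qual %||% rep(30L, length(rc)))
  lf <- length(fc); lr <- length(rc)

  best_ov <- 0L; best_id <- -1
  for (ov in seq(min_overlap, min(lf, lr))) {
    idd <- mean(fc[(lf - ov + 1):lf] == rc[1:ov])
    if (idd >= min_identity && (idd > best_id ||
                                (idd == best_id && ov > best_ov))) {
      best_id <- idd; best_ov <- ov
    }
  }
  if (best_ov == 0L)
    return(list(assembled = FALSE, fwd = fwd, rev = rev,
                fwd_qual = fwd_qual, rev_qual = rev_qual))

  ov <- best_ov
  fo <- (lf - ov + 1):lf
  f_ch <- fc[fo]; r_ch <- rc[1:ov]
  f_q <- fq[fo]; r_q <- rq[1:ov]
  take_r <- f_ch != r_ch & r_q > f_q
  mid <- ifelse(take_r, r_ch, f_ch)
  midq <- pmax(f_q, r_q)
  list(
    assembled = TRUE,
    seq = paste(c(fc[seq_len(lf - ov)], mid, rc[-(1:ov)]), collapse = ""),
    qual = as.integer(c(fq[seq_len(lf - ov)], midq, rq[-(1:ov)])),
    overlap_len = ov, identity = best_id
  )
}

#' Build a reference alignment object
#'
#' Wraps a set of gapped reference rows sharing one width into the lookup
#' structure used by [align_to_reference()]: ungapped sequences, the map
#' from each reference's ungapped positions to alignment columns, and k-mer
#' sets for the nearest-reference prescreen.
#'
#' @param ids reference identifiers.
#' @param rows gapped (or ungapped) rows, all the same width.
#' @param k word size for the prescreen.
#' @return a `reference_alignment`.
#' @export
reference_alignment <- function(ids, rows, k = 8) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1)
  width <- unique(nchar(rows))
  if (length(width) != 1) stop("reference rows must share one width")
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  col_map <- lapply(rows, function(r) {
    which(strsplit(r, "", fixed = TRUE)[[1]] != "-")
  })
  kmers <- lapply(ungapped, function(s) unique(kmer_ids(s, k)))
  structure(list(ids = ids, rows = rows, width = width,
                 ungapped = ungapped, col_map = col_map,
                 kmers = kmers, k = k),
            class = "reference_alignment")
}

#' @rdname reference_alignment
#' @param refs a [build_reference_set()] result (rows are ungapped, so the
#'   alignment width equals the amplicon length).
#' @export
as_reference_alignment <- function(refs, k = 8) {
  reference_alignment(refs$taxon_id, refs$sequence, k = k)
}

#' Align one sequence into reference coordinates
#'
#' Picks the nearest reference by shared k-mers, aligns the query globally
#' against it (Needleman-Wunsch, end-gap free in the reference), and
#' projects the query onto the reference's alignment columns. Query bases
#' falling in insertions relative to the reference are dropped, so
#' ungapping the returned row recovers a subsequence of the query.
#'
#' @param seq ungapped query (may contain N).
#' @param ref_aln a [reference_alignment()].
#' @return list with `row` (gapped string of width `ref_aln$width`),
#'   `ref_id` (nearest reference) and `score`.
#' @export
align_to_reference <- function(seq, ref_aln) {
  stopifnot(inherits(ref_aln, "reference_alignment"))
  if (!nzchar(seq)) stop("empty query sequence")
  q <- unique(kmer_ids(seq, ref_aln$k))
  shared <- vapply(ref_aln$kmers,
                   function(s) length(intersect(q, s)), numeric(1))
  best <- which.max(shared)

  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 2, mismatch = -3, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq, subject = ref_aln$ungapped[[best]],
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 2)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                  "", fixed = TRUE)[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                  "", fixed = TRUE)[[1]]
  s_start <- pa@subject@range@start

  row <- rep("-", ref_aln$width)
  ref_base <- sub != "-"
  upos <- s_start - 1L + cumsum(ref_base)     # ungapped ref position
  keep <- ref_base & pat != "-"
  row[ref_aln$col_map[[best]][upos[keep]]] <- pat[keep]
  list(row = paste(row, collapse = ""), ref_id = ref_aln$ids[[best]],
       score = Biostrings::score(pa))
}

#' Construct an alignment matrix
#'
#' A fixed-width multiple alignment in reference coordinates: one gapped
#' row per retained sequence plus bookkeeping for trimmed columns.
#'
#' @param seq_id,row,library_id,origin parallel vectors (`origin` is
#'   `"assembled"` or `"concatenated"`).
#' @param col_index original column indices of the current columns.
#' @param removed_columns original indices of columns removed so far.
#' @return an `alignment_matrix`.
#' @export
alignment_matrix <- function(seq_id, row, library_id = NA_character_,
                             origin = "assembled", col_index = NULL,
                             removed_columns = integer(0)) {
  width <- unique(nchar(row))
  if (length(width) > 1) stop("all rows must share one width")
  if (length(width) == 0) width <- 0L
  n <- length(row)
  structure(list(
    width = width,
    seq_id = as.character(seq_id),
    library_id = rep_len(as.character(library_id), n),
    row = as.character(row),
    origin = rep_len(origin, n),
    col_index = col_index %||% seq_len(width),
    removed_columns = as.integer(removed_columns)
  ), class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("alignment_matrix: %d sequence(s) x %d column(s); %d column(s) trimmed\n",
              length(x$row), x$width, length(x$removed_columns)))
  invisible(x)
}

# character matrix view (rows x columns)
aln_char_matrix <- function(aln) {
  if (length(aln$row) == 0)
    return(matrix(character(0), nrow = 0, ncol = aln$width))
  matrix(unlist(strsplit(aln$row, "", fixed = TRUE), use.names = FALSE),
         nrow = length(aln$row), ncol = aln$width, byrow = TRUE,
         dimnames = list(aln$seq_id, NULL))
}

#' Non-gap character counts per row
#'
#' `N` counts as a non-gap character; only `-` is a gap.
#' @param aln an `alignment_matrix`.
#' @return named integer vector.
#' @export
nongap_counts <- function(aln) {
  setNames(nchar(gsub("-", "", aln$row, fixed = TRUE)), aln$seq_id)
}

#' Concatenate two non-overlapping aligned reads into one row
#'
#' For clones whose end-reads do not overlap, the two aligned rows are
#' combined into a single row with gap characters spanning the unread
#' interior, mirroring the gapped-concatenation step of the original
#' workflow.
#'
#' @param fwd_row,rev_row gapped rows of equal width (reference
#'   coordinates). The forward row's rightmost non-gap column must lie
#'   before the reverse row's leftmost non-gap column.
#' @return list with `row` and the interior gap span (`gap_from`,
#'   `gap_to`; zero-length spans allowed).
#' @export
concatenate_nonoverlapping <- function(fwd_row, rev_row) {
  stopifnot(nchar(fwd_row) == nchar(rev_row))
  f <- strsplit(fwd_row, "", fixed = TRUE)[[1]]
  r <- strsplit(rev_row, "", fixed = TRUE)[[1]]
  f_ng <- which(f != "-"); r_ng <- which(r != "-")
  if (!length(f_ng) || !length(r_ng))
    stop("both rows must contain non-gap characters")
  f_hi <- max(f_ng); r_lo <- min(r_ng)
  if (f_hi >= r_lo)
    stop(sprintf(
      "rows overlap in reference columns: forward spans %d-%d, reverse spans %d-%d",
      min(f_ng), f_hi, r_lo, max(r_ng)))
  out <- rep("-", length(f))
  out[f_ng] <- f[f_ng]
  out[r_ng] <- r[r_ng]
  list(row = paste(out, collapse = ""),
       gap_from = f_hi + 1L, gap_to = r_lo - 1L)
}

#' Remove high-gap alignment columns
#'
#' Drops every column whose gap fraction (counting `-` only; `N` is not a
#' gap) strictly exceeds `max_gap_frac`. Original column indices of removed
#' columns are recorded, and retained columns keep their relative order, so
#' trimming is idempotent and reversible on paper.
#'
#' @param aln an `alignment_matrix`.
#' @param max_gap_frac threshold gap fraction (default 0.80; strict `>`).
#' @return trimmed `alignment_matrix`.
#' @export
trim_gap_columns <- function(aln, max_gap_frac = 0.80) {
  stopifnot(inherits(aln, "alignment_matrix"), length(aln$row) > 0)
  m <- aln_char_matrix(aln)
  gap_frac <- colMeans(m == "-")
  drop <- gap_frac > max_gap_frac
  if (!any(drop)) return(aln)
  keep <- which(!drop)
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  alignment_matrix(
    seq_id = aln$seq_id, row = unname(rows), library_id = aln$library_id,
    origin = aln$origin, col_index = aln$col_index[keep],
    removed_columns = sort(c(aln$removed_columns, aln$col_index[which(drop)]))
  )
}

#' Remove sequences left too short after trimming
#'
#' @param aln a trimmed `alignment_matrix`.
#' @param min_nongap minimum non-gap characters to retain a row
#'   (default 300; a row with exactly `min_nongap` is kept).
#' @return list with `alignment` (retained rows) and `removed` (data frame
#'   of `seq_id`, `library_id`, `nongap`).
#' @export
filter_short <- function(aln, min_nongap = 300) {
  stopifnot(inherits(aln, "alignment_matrix"))
  ng <- nongap_counts(aln)
  keep <- ng >= min_nongap
  removed <- data.frame(seq_id = aln$seq_id[!keep],
                        library_id = aln$library_id[!keep],
                        nongap = unname(ng[!keep]),
                        stringsAsFactors = FALSE)
  kept <- alignment_matrix(
    seq_id = aln$seq_id[keep], row = aln$row[keep],
    library_id = aln$library_id[keep], origin = aln$origin[keep],
    col_index = aln$col_index, removed_columns = aln$removed_columns
  )
  list(alignment = kept, removed = removed)
}

#' Write / read a fixed-width alignment as FASTA
#'
#' @param aln an `alignment_matrix`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(
    setNames(Biostrings::BStringSet(aln$row), aln$seq_id), path)
  invisible(path)
}
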