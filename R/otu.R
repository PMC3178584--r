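# OTU assignment: pairwise distances on the trimmed alignment (one internal
# gap run = one difference, terminal gaps ignored), average-neighbor
# clustering at a distance cutoff, representative picking, OTU tables and
# consensus relabeling.

#' Pairwise distances between aligned sequences
#'
#' Distance between two rows of a fixed-width alignment, following the
#' convention of classic clone-library distance tools:
#' * columns where both rows are gapped are ignored;
#' * terminal gap runs (before a row's first, or after its last, non-gap
#'   character) are ignored;
#' * a maximal internal run of gaps in one row opposite bases in the other
#'   counts as ONE difference (and one compared column) regardless of run
#'   length — so the unread interior of a concatenated read pair is not
#'   penalised per column;
#' * `N` matches nothing: paired with a base (or another `N`) it is a
#'   difference; paired with a gap the column is ignored;
#' * distance = differences / compared columns.
#'
#' In rows of origin `"concatenated"` the internal gap runs are the unread
#' interior between the two end-reads, i.e. absence of data rather than
#' deletion; with `concat_missing = TRUE` (the default) those columns are
#' ignored pairwise instead of being charged as gap differences. With
#' `each_gap = TRUE` every internal gap column counts separately (the
#' "eachgap" convention).
#'
#' @param aln an [alignment_matrix()].
#' @param each_gap penalise each gap column separately instead of one per
#'   run.
#' @param concat_missing treat internal gaps of concatenated rows as
#'   missing data.
#' @return symmetric numeric matrix with zero diagonal, dimnames = seq ids.
#'   A pair with no comparable columns gets distance 1 with a warning.
#' @export
pairwise_distance <- function(aln, each_gap = FALSE, concat_missing = TRUE) {
  stopifnot(inherits(aln, "alignment_matrix"))
  n <- length(aln$row)
  ids <- aln$seq_id
  codes <- matrix(0L, nrow = n, ncol = aln$width)
  for (i in seq_len(n)) codes[i, ] <- seq_to_codes(aln$row[i])
  st <- integer(n); en <- integer(n)
  for (i in seq_len(n)) {
    ng <- which(codes[i, ] != 0L)
    if (!length(ng)) stop("row ", ids[i], " is all gaps")
    st[i] <- ng[1]; en[i] <- ng[length(ng)]
    if (concat_missing && identical(aln$origin[i], "concatenated")) {
      span <- st[i]:en[i]
      miss <- span[codes[i, span] == 0L]
      codes[i, miss] <- 6L               # missing: ignored pairwise
    }
  }
  n_runs <- function(b) sum(b & !c(FALSE, b[-length(b)]))

  d <- matrix(0, n, n, dimnames = list(ids, ids))
  warned <- FALSE
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      lo <- max(st[i], st[j]); hi <- min(en[i], en[j])
      if (lo > hi) {
        d[i, j] <- d[j, i] <- 1; warned <- TRUE
        next
      }
      x <- codes[i, lo:hi]; y <- codes[j, lo:hi]
      valid <- x != 6L & y != 6L
      x <- x[valid]; y <- y[valid]
      both <- x != 0L & y != 0L
      diffs <- sum(both & (x != y | x == 5L))
      gx <- x == 0L & y >= 1L & y <= 4L
      gy <- y == 0L & x >= 1L & x <= 4L
      if (each_gap) {
        gruns <- sum(gx) + sum(gy)
      } else {
        gruns <- n_runs(gx) + n_runs(gy)
      }
      compared <- sum(both) + gruns
      if (compared == 0) {
        d[i, j] <- d[j, i] <- 1; warned <- TRUE
      } else {
        d[i, j] <- d[j, i] <- (diffs + gruns) / compared
      }
    }
  }
  if (warned)
    warning("some sequence pairs had no comparable columns; distance set to 1")
  d
}

#' Average-neighbor (average-linkage) OTU clustering
#'
#' Agglomerative clustering: repeatedly merge the pair of clusters with the
#' smallest mean inter-cluster distance while that mean does not exceed the
#' cutoff. Ties are broken towards the pair containing the
#' lexicographically smallest member id (then the smallest id in the other
#' cluster), which makes the partition invariant to input order. Average
#' distances are maintained exactly with the Lance-Williams update.
#'
#' @param dm symmetric distance matrix with dimnames (e.g. from
#'   [pairwise_distance()]).
#' @param cutoff distance cutoff (default 0.03, i.e. 97% similarity).
#' @return an `otu_partition`: list with `cutoff` and `clusters` (list of
#'   member-id vectors, each sorted; clusters ordered by size then id).
#' @export
average_neighbor_cluster <- function(dm, cutoff = 0.03) {
  ids <- rownames(dm)
  stopifnot(!is.null(ids), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n == 1)
    return(structure(list(cutoff = cutoff, clusters = list(ids)),
                     class = "otu_partition"))

  D <- dm
  active <- rep(TRUE, n)
  members <- as.list(ids)
  sizes <- rep(1L, n)
  diag(D) <- Inf

  repeat {
    act <- which(active)
    if (length(act) < 2) break
    sub <- D[act, act, drop = FALSE]
    dmin <- min(sub)
    if (dmin > cutoff) break
    hit <- which(sub <= dmin + 0, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # deterministic tie-break on member ids
    key1 <- character(nrow(hit)); key2 <- character(nrow(hit))
    for (h in seq_len(nrow(hit))) {
      a <- members[[act[hit[h, 1]]]]; b <- members[[act[hit[h, 2]]]]
      lo <- min(a[1], b[1]); hi2 <- if (lo == a[1]) b[1] else a[1]
      key1[h] <- lo; key2[h] <- hi2
    }
    pick <- order(key1, key2)[1]
    i <- act[hit[pick, 1]]; j <- act[hit[pick, 2]]

    # Lance-Williams average-linkage update into slot i
    ni <- sizes[i]; nj <- sizes[j]
    upd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- upd; D[, i] <- upd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- ni + nj
  }
  clusters <- members[active]
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, "", 1))
  structure(list(cutoff = cutoff, clusters = clusters[ord]),
            class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("otu_partition: %d cluster(s) at cutoff %.3f\n",
              length(x$clusters), x$cutoff))
  invisible(x)
}

#' Pick the representative sequence of a cluster
#'
#' The member minimising total distance to all other members; ties go to
#' the smallest id.
#'
#' @param cluster character vector of member ids.
#' @param dm distance matrix covering the members.
#' @return a single seq id.
#' @export
pick_representative <- function(cluster, dm) {
  stopifnot(length(cluster) >= 1)
  if (length(cluster) == 1) return(cluster)
  cl <- sort(cluster)
  tot <- rowSums(dm[cl, cl, drop = FALSE])
  cl[which.min(tot)]          # which.min takes the first (smallest id) tie
}

#' Build the OTU x library count table
#'
#' @param partition an [average_neighbor_cluster()] result.
#' @param library_of named character vector mapping seq id -> library id.
#' @param dm optional distance matrix used to pick representatives and name
#'   OTUs `"<library> <index>"` after the representative's library.
#' @return an `otu_table`: list with `counts` (OTU x library integer
#'   matrix), `representative`, `members`, and (once
#'   [relabel_otu_taxonomy()] has run) `lineage`.
#' @export
build_otu_table <- function(partition, library_of, dm = NULL) {
  stopifnot(inherits(partition, "otu_partition"))
  # canonical OTU order: size descending, then smallest member id, so the
  # table is independent of the clustering input order
  cl <- lapply(partition$clusters, sort)
  partition$clusters <- cl[order(-vapply(cl, length, integer(1)),
                                 vapply(cl, `[`, "", 1))]
  all_ids <- unlist(partition$clusters)
  unmapped <- setdiff(all_ids, names(library_of))
  if (length(unmapped))
    stop("sequences not mapped to a library: ",
         paste(head(unmapped, 5), collapse = ", "))
  libs <- sort(unique(unname(library_of[all_ids])))
  k <- length(partition$clusters)
  counts <- matrix(0L, nrow = k, ncol = length(libs),
                   dimnames = list(NULL, libs))
  reps <- character(k)
  for (o in seq_len(k)) {
    cl <- partition$clusters[[o]]
    tab <- table(factor(unname(library_of[cl]), levels = libs))
    counts[o, ] <- as.integer(tab)
    reps[o] <- if (is.null(dm)) sort(cl)[1] else pick_representative(cl, dm)
  }
  labels <- sprintf("%s %03d", unname(library_of[reps]), seq_len(k))
  rownames(counts) <- labels
  structure(list(counts = counts, representative = setNames(reps, labels),
                 members = setNames(partition$clusters, labels),
                 cutoff = partition$cutoff, lineage = NULL),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTU(s) x %d library(ies), %d sequence(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Consensus taxonomy of one OTU from its members
#'
#' At each rank, a strict-majority label among members carrying a
#' classified label at that rank is adopted (reassigning members'
#' "unclassified" calls to the dominant label). If every member is
#' unclassified at genus, the genus is named after the nearest reference
#' taxon of the representative sequence (suffix `-like`), standing in for
#' manual phylogeny-based naming.
#'
#' @param lineages data frame of member lineages (six rank columns, one row
#'   per member; "unclassified" where a rank was not called).
#' @param rep_seq optional ungapped representative sequence.
#' @param refs optional reference set used for nearest-reference naming.
#' @return named character vector over the six ranks.
#' @export
relabel_otu_taxonomy <- function(lineages, rep_seq = NULL, refs = NULL) {
  if (is.null(lineages) || nrow(lineages) == 0) stop("empty cluster")
  out <- setNames(rep("unclassified", 6), RANKS)
  for (r in RANKS) {
    labs <- lineages[[r]]
    labs <- labs[!is.na(labs) & labs != "unclassified"]
    if (!length(labs)) break
    tab <- sort(table(labs), decreasing = TRUE)
    if (length(tab) == 1 || tab[1] * 2 > length(labs)) {
      out[[r]] <- names(tab)[1]
    } else break                       # no strict majority: stop here
  }
  glabs <- lineages[["genus"]]
  no_genus_at_all <- !any(!is.na(glabs) & glabs != "unclassified")
  if (out[["genus"]] == "unclassified" && no_genus_at_all &&
      !is.null(rep_seq) && !is.null(refs)) {
    q <- unique(kmer_ids(rep_seq, 8))
    shared <- vapply(refs$sequence, function(s) {
      length(intersect(q, unique(kmer_ids(s, 8))))
    }, numeric(1))
    out[["genus"]] <- paste0(refs$genus[which.max(shared)], "-like")
  }
  out
}

#' Relabel every OTU in a table from its members' decisions
#'
#' @param table an [build_otu_table()] result.
#' @param decisions named list of `consensus_decision`s (names = clone ids
#'   matching the clustered sequence ids).
#' @param rep_seqs optional named ungapped sequences for representatives.
#' @param refs optional reference set for nearest-reference naming.
#' @return the table with a `lineage` data frame (one row per OTU).
#' @export
relabel_otu_table <- function(table, decisions, rep_seqs = NULL,
                              refs = NULL) {
  stopifnot(inherits(table, "otu_table"))
  lin <- lapply(names(table$members), function(lbl) {
    mem <- table$members[[lbl]]
    df <- do.call(rbind, lapply(mem, function(id) {
      as.data.frame(as.list(decisions[[id]]$lineage),
                    stringsAsFactors = FALSE)
    }))
    rs <- if (!is.null(rep_seqs)) rep_seqs[[table$representative[[lbl]]]]
    relabel_otu_taxonomy(df, rep_seq = rs, refs = refs)
  })
  table$lineage <- as.data.frame(do.call(rbind, lin),
                                 stringsAsFactors = FALSE)
  rownames(table$lineage) <- rownames(table$counts)
  table
}

#' Write an OTU table (counts, lineage, representative) as TSV
#'
#' @param table an `otu_table`.
#' @param path output file.
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu = rownames(table$counts),
                   representative = unname(table$representative),
                   stringsAsFactors = FALSE)
  if (!is.null(table$lineage)) df <- cbind(df, table$lineage)
  df <- cbind(df, as.data.frame(table$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
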