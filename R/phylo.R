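# Tree-based community comparison: neighbor-joining tree over OTU
# representatives, unweighted UniFrac, permutation significance tests and
# principal-coordinates ordination.

#' Neighbor-joining tree rooted on an outgroup
#'
#' Builds a neighbor-joining tree from a distance matrix, clamps negative
#' branch lengths to zero (moving the deficit onto an adjacent branch so
#' leaf-to-leaf path lengths through the node are preserved), and roots the
#' tree at the midpoint of the outgroup's branch.
#'
#' @param dm symmetric distance matrix with dimnames; at least 3 taxa.
#' @param outgroup row name used for rooting.
#' @return a rooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm, outgroup) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3)
  if (!outgroup %in% rownames(dm))
    stop("outgroup '", outgroup, "' not present in the distance matrix")
  tr <- ape::nj(dm)

  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]
    if (len >= 0) next       # may have been fixed by an earlier transfer
    node <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == node | tr$edge[, 2] == node), e)
    if (length(sib)) {
      s <- sib[which.max(tr$edge.length[sib])]
      tr$edge.length[s] <- tr$edge.length[s] + len
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0

  rt <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  root_node <- ape::Ntip(rt) + 1L
  ce <- which(rt$edge[, 1] == root_node)
  if (length(ce) == 2) {
    total <- sum(rt$edge.length[ce])
    rt$edge.length[ce] <- total / 2
  }
  rt
}

#' Leaf-by-library membership from an OTU table
#'
#' @param table an [build_otu_table()] result.
#' @return integer matrix (leaves = OTU representatives x libraries) of
#'   member counts; presence is what the unweighted metric uses.
#' @export
otu_membership <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  rownames(m) <- unname(table$representative)
  m
}

# presence propagation over a postorder tree; returns per-node logical
.node_presence <- function(tr, present_tips) {
  ntip <- length(tr$tip.label)
  pres <- logical(ntip + tr$Nnode)
  pres[seq_len(ntip)] <- tr$tip.label %in% present_tips
  for (e in seq_len(nrow(tr$edge))) {
    pres[tr$edge[e, 1]] <- pres[tr$edge[e, 1]] || pres[tr$edge[e, 2]]
  }
  pres
}

#' Unweighted UniFrac distance between two libraries
#'
#' The fraction of branch length, in the subtree induced by the two
#' libraries' leaves, that leads exclusively to leaves of one library.
#' 0 when the libraries occupy identical leaf sets; 1 when they occupy
#' disjoint clades with no shared internal branches.
#'
#' @param tree rooted `phylo` whose tips cover all leaves with presence.
#' @param membership matrix leaves x libraries (counts or logical).
#' @param a,b library (column) names to compare.
#' @return distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(tree, membership, a, b) {
  la <- rownames(membership)[membership[, a] > 0]
  lb <- rownames(membership)[membership[, b] > 0]
  if (!length(la) || !length(lb))
    stop("each compared library needs at least one leaf")
  leaves <- union(la, lb)
  if (setequal(la, lb)) return(0)
  if (length(leaves) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, leaves)
  }
  tr <- stats::reorder(tree, "postorder")
  pa <- .node_presence(tr, la)
  pb <- .node_presence(tr, lb)
  child <- tr$edge[, 2]
  below_a <- pa[child]; below_b <- pb[child]
  either <- below_a | below_b
  unique_len <- sum(tr$edge.length[xor(below_a, below_b)])
  total_len <- sum(tr$edge.length[either])
  if (total_len == 0) return(0)
  unique_len / total_len
}

#' All pairwise unweighted UniFrac distances
#'
#' @param tree rooted `phylo`.
#' @param membership leaves x libraries matrix.
#' @return symmetric distance matrix over libraries.
#' @export
unifrac_matrix <- function(tree, membership) {
  libs <- colnames(membership)
  d <- matrix(0, length(libs), length(libs), dimnames = list(libs, libs))
  for (i in seq_along(libs)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- unweighted_unifrac(tree, membership,
                                             libs[i], libs[j])
  }
  d
}

#' Permutation significance of between-group UniFrac
#'
#' Libraries are pooled into groups (e.g. host-diet bins); for each group
#' pair the observed pooled UniFrac distance is compared to a null
#' distribution obtained by randomly reassigning the leaves' membership
#' rows. P-values use the permutation-inclusive estimator
#' `(1 + #{perm >= obs}) / (1 + n_perm)` and are Bonferroni-corrected
#' across the group pairs tested.
#'
#' @param tree rooted `phylo`.
#' @param membership leaves x libraries matrix.
#' @param grouping named character vector: library -> group label; at least
#'   two groups.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return data frame: `group_a`, `group_b`, `observed`, `p`,
#'   `p_bonferroni`.
#' @export
unifrac_permutation_test <- function(tree, membership, grouping,
                                     n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  grouping <- grouping[colnames(membership)]
  groups <- sort(unique(unname(grouping)))
  if (length(groups) < 2) stop("at least two groups are required")
  # canonical leaf order makes results independent of input row order
  membership <- membership[order(rownames(membership)), , drop = FALSE]

  pool <- function(memb) {
    out <- vapply(groups, function(g) {
      rowSums(memb[, names(grouping)[grouping == g], drop = FALSE])
    }, numeric(nrow(memb)))
    rownames(out) <- rownames(memb)
    out
  }
  obs_pooled <- pool(membership)
  pairs <- utils::combn(groups, 2)
  obs <- apply(pairs, 2, function(pr) {
    unweighted_unifrac(tree, obs_pooled, pr[1], pr[2])
  })

  exceed <- matrix(0, nrow = ncol(pairs), ncol = 1)
  with_seed(seed, {
    for (it in seq_len(n_perm)) {
      perm <- membership[sample(nrow(membership)), , drop = FALSE]
      rownames(perm) <- sort(rownames(membership))
      pp <- pool(perm)
      for (ci in seq_len(ncol(pairs))) {
        v <- unweighted_unifrac(tree, pp, pairs[1, ci], pairs[2, ci])
        if (v >= obs[ci]) exceed[ci] <- exceed[ci] + 1
      }
    }
  })
  p <- (1 + exceed[, 1]) / (1 + n_perm)
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             observed = obs, p = p,
             p_bonferroni = pmin(1, p * ncol(pairs)),
             stringsAsFactors = FALSE)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centred Gower matrix eigendecomposition. Negative eigenvalues
#' (non-Euclidean input) are reported, never silently dropped; percent
#' variance is relative to the sum of positive eigenvalues.
#'
#' @param dm symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (rows = items, ordered by eigenvalue),
#'   `eigenvalues`, `percent_variance`.
#' @export
pcoa <- function(dm) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("input must be a symmetric distance matrix")
  if (any(abs(diag(dm)) > 1e-8)) stop("diagonal must be zero")
  n <- nrow(dm)
  cs <- stats::cmdscale(dm, k = n - 1, eig = TRUE)
  eig <- cs$eig
  pos <- sum(eig[eig > 0])
  list(coordinates = cs$points,
       eigenvalues = eig,
       percent_variance = if (pos > 0) 100 * eig / pos else eig * 0)
}

#' Write a classic UniFrac environment file
#'
#' One line per (leaf, library) with a positive count:
#' `leaf<TAB>library<TAB>count`.
#'
#' @param membership leaves x libraries count matrix.
#' @param path output file.
#' @export
write_unifrac_env <- function(membership, path) {
  idx <- which(membership > 0, arr.ind = TRUE)
  df <- data.frame(leaf = rownames(membership)[idx[, 1]],
                   library = colnames(membership)[idx[, 2]],
                   count = membership[idx])
  df <- df[order(df$leaf, df$library), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
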