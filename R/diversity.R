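# Alpha diversity (Chao1, Shannon, Good's coverage, analytic rarefaction)
# and beta diversity (shared-OTU similarity, unique-OTU proportions) on OTU
# count vectors and tables.

.check_counts <- function(counts) {
  counts <- unname(counts[!is.na(counts)])
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("at least one sequence is required")
  counts
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + n1 (n1 - 1) / (2 (n2 + 1))`, with `n1` singleton and `n2`
#' doubleton OTUs; the bias-corrected form stays defined when no doubleton
#' exists. Always at least the observed richness.
#'
#' @param counts nonnegative integer abundances (zeros ignored).
#' @return numeric estimate.
#' @export
chao1 <- function(counts) {
  v <- .check_counts(counts)
  n1 <- sum(v == 1); n2 <- sum(v == 2)
  length(v) + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' Shannon diversity and evenness
#'
#' `H = -sum p_i ln p_i` (natural log by default) and evenness
#' `H / ln(S_obs)`. A single-OTU community has `H = 0`; its evenness is the
#' indeterminate 0/0 and is reported as 1 with `evenness_defined = FALSE`.
#'
#' @param counts nonnegative integer abundances.
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @return list with `H`, `evenness`, `evenness_defined`.
#' @export
shannon <- function(counts, base = exp(1)) {
  v <- .check_counts(counts)
  p <- v / sum(v)
  H <- -sum(p * log(p, base = base))
  S <- length(v)
  if (S == 1) list(H = 0, evenness = 1, evenness_defined = FALSE)
  else list(H = H, evenness = H / log(S, base = base),
            evenness_defined = TRUE)
}

#' Good's coverage
#'
#' `1 - n1 / N`: the estimated probability that one more sequence would
#' fall in an already-observed OTU.
#'
#' @param counts nonnegative integer abundances.
#' @return fraction in `[0, 1]`.
#' @export
goods_coverage <- function(counts) {
  v <- .check_counts(counts)
  1 - sum(v == 1) / sum(v)
}

#' Analytic rarefaction curve
#'
#' Expected richness (and its variance) of a random subsample of `m`
#' sequences drawn without replacement:
#' `E[S_m] = sum_i (1 - C(N - c_i, m) / C(N, m))`, evaluated with
#' log-gamma for numerical stability. The variance follows the classic
#' hypergeometric formula including pairwise covariance terms.
#'
#' @param counts nonnegative integer abundances.
#' @param depths increasing subsample sizes, all `<= N`; by default 20
#'   evenly spaced depths up to `N`.
#' @return data frame with `depth`, `expected_richness`, `variance`.
#' @export
rarefaction <- function(counts, depths = NULL) {
  v <- .check_counts(counts)
  N <- sum(v)
  if (is.null(depths)) depths <- unique(round(seq(1, N, length.out = 20)))
  depths <- as.integer(depths)
  if (any(depths < 1) || any(depths > N))
    stop("depths must lie between 1 and the library size N = ", N)

  # P(OTU i entirely missed in a subsample of m) on log scale
  miss <- function(ci, m) {
    ifelse(N - ci < m, 0, exp(lchoose(N - ci, m) - lchoose(N, m)))
  }
  res <- lapply(depths, function(m) {
    qi <- vapply(v, miss, numeric(1), m = m)
    E <- sum(1 - qi)
    var_diag <- sum(qi * (1 - qi))
    cov_sum <- 0
    S <- length(v)
    if (S >= 2) {
      for (i in 1:(S - 1)) for (j in (i + 1):S) {
        qij <- if (N - v[i] - v[j] < m) 0 else
          exp(lchoose(N - v[i] - v[j], m) - lchoose(N, m))
        cov_sum <- cov_sum + (qij - qi[i] * qi[j])
      }
    }
    c(E = E, V = var_diag + 2 * cov_sum)
  })
  out <- do.call(rbind, res)
  data.frame(depth = depths, expected_richness = out[, "E"],
             variance = pmax(out[, "V"], 0))
}

#' Membership-based similarity between two libraries
#'
#' @param a,b abundance vectors indexed on the same OTU set (same length
#'   or both named over a common OTU universe).
#' @return list with `jaccard` (shared / union OTUs) and
#'   `shared_seq_fraction` (fraction of the two libraries' pooled
#'   sequences that fall in shared OTUs).
#' @export
shared_otu_similarity <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    univ <- union(names(a), names(b))
    a <- setNames(a[univ], univ); a[is.na(a)] <- 0
    b <- setNames(b[univ], univ); b[is.na(b)] <- 0
  }
  stopifnot(length(a) == length(b))
  if (sum(a) + sum(b) == 0) stop("both libraries are empty")
  pa <- a > 0; pb <- b > 0
  un <- sum(pa | pb)
  sh <- pa & pb
  list(jaccard = if (un == 0) 0 else sum(sh) / un,
       shared_seq_fraction = (sum(a[sh]) + sum(b[sh])) / (sum(a) + sum(b)))
}

#' Proportion of each library's OTUs found in no other library of a group
#'
#' @param table an [build_otu_table()] result.
#' @param group library ids forming the comparison group (default: all).
#' @return named numeric vector, one fraction per library in the group.
#' @export
unique_otu_proportion <- function(table, group = colnames(table$counts)) {
  stopifnot(inherits(table, "otu_table"), length(group) >= 1)
  cnt <- table$counts[, group, drop = FALSE]
  pres <- cnt > 0
  vapply(group, function(l) {
    mine <- pres[, l]
    if (!any(mine)) return(NA_real_)
    others <- pres[, setdiff(group, l), drop = FALSE]
    sum(mine & rowSums(others) == 0) / sum(mine)
  }, numeric(1))
}

#' Per-library alpha-diversity summary
#'
#' One row per library: sequence count, observed richness, Chao1, Shannon
#' diversity and evenness, Good's coverage.
#'
#' @param table an `otu_table`.
#' @return data frame.
#' @export
diversity_summary <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  libs <- colnames(table$counts)
  do.call(rbind, lapply(libs, function(l) {
    v <- table$counts[, l]
    sh <- shannon(v)
    data.frame(library = l, n = sum(v), s_obs = sum(v > 0),
               chao1 = chao1(v), shannon = sh$H, evenness = sh$evenness,
               coverage = goods_coverage(v), stringsAsFactors = FALSE)
  }))
}

#' All pairwise beta-diversity comparisons in a table
#'
#' @param table an `otu_table`.
#' @return data frame with one row per unordered library pair: `jaccard`
#'   and `shared_seq_fraction`.
#' @export
beta_diversity_table <- function(table) {
  libs <- colnames(table$counts)
  pairs <- utils::combn(libs, 2)
  do.call(rbind, apply(pairs, 2, function(pr) {
    s <- shared_otu_similarity(table$counts[, pr[1]], table$counts[, pr[2]])
    data.frame(library_a = pr[1], library_b = pr[2],
               jaccard = s$jaccard,
               shared_seq_fraction = s$shared_seq_fraction,
               stringsAsFactors = FALSE)
  }))
}
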