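# Shared fixtures and independent oracles used across the suite.

ranks <- c("domain", "phylum", "class", "order", "family", "genus")

# one medium reference set reused by several files (built once per run)
fixture_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_reference_set(5, 3, seed = 42)
    cache
  }
})

# brute-force average-linkage clustering: recompute every cluster-pair mean
# from the original matrix at every step (independent of the Lance-Williams
# implementation under test)
oracle_average_linkage <- function(dm, cutoff) {
  clusters <- as.list(rownames(dm))
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL; best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- mean(dm[clusters[[i]], clusters[[j]]])
      pick <- FALSE
      if (d < best_d - 1e-15) pick <- TRUE
      else if (abs(d - best_d) <= 1e-15 && !is.null(best)) {
        # tie: pair containing the smallest id, then the smallest other id
        cand <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cur <- sort(c(min(clusters[[best[1]]]), min(clusters[[best[2]]])))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
          pick <- TRUE
      }
      if (pick) { best <- c(i, j); best_d <- d }
    }
    if (best_d > cutoff) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
  }
  clusters
}

# canonical form of a partition for comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, "", 1))]
}

random_dist_matrix <- function(n, max_d = 0.08) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.001, max_d)
  d <- d + t(d)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  d
}

# build a classification object directly (for consensus decision tests)
mk_classification <- function(genus = "Genus_1", family = "Family_1",
                              order = "Order_1", class = "Class_1",
                              phylum = "Phylum_1", domain = "Bacteria",
                              supports = rep(100, 6)) {
  labels <- c(domain = domain, phylum = phylum, class = class,
              order = order, family = family, genus = genus)
  structure(list(labels = labels,
                 supports = setNames(supports, ranks)),
            class = "classification")
}

# Monte-Carlo rarefaction oracle: repeated subsampling without replacement
mc_rarefaction <- function(counts, m, n_rep, seed) {
  counts <- counts[counts > 0]
  labels <- rep(seq_along(counts), counts)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- replicate(n_rep, length(unique(labels[sample.int(length(labels), m)])))
  list(mean = mean(s), se = stats::sd(s) / sqrt(n_rep))
}
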