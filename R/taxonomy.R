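# Taxonomy: k-mer naive-Bayes genus classifier with bootstrap confidence,
# rank-threshold consensus across 5'/3'/full-length classifications,
# conflict-based chimera flagging, and endosymbiont/chloroplast partitioning.

#' Bootstrap-support thresholds per rank
#'
#' A rank label is accepted only with bootstrap support above its threshold:
#' strictly greater than 75 at genus, 80 at family and 95 at order, and
#' exactly 100 at class. Phylum and domain (not covered by the printed
#' ladder) inherit the class rule, keeping the ladder monotone.
#'
#' @param genus,family,order,class_ percent thresholds.
#' @return named numeric vector over the six ranks (domain first).
#' @export
rank_thresholds <- function(genus = 75, family = 80, order = 95,
                            class_ = 100) {
  thr <- c(domain = class_, phylum = class_, class = class_,
           order = order, family = family, genus = genus)
  if (any(diff(thr) > 0))
    stop("thresholds must be non-increasing from domain to genus")
  thr
}

# does a support value pass a rank threshold? strict > below 100,
# equality required at 100
.passes <- function(support, thr) {
  ifelse(thr >= 100, support >= 100, support > thr)
}

#' Train the k-mer naive-Bayes taxonomy classifier
#'
#' Per genus, estimates the probability that each k-mer word occurs in a
#' member sequence, with add-half smoothing: `(m_w + 0.5) / (M + 1)` where
#' `m_w` counts members containing word `w` and `M` is the genus size.
#'
#' @param refs a [build_reference_set()]-shaped data frame (needs the six
#'   rank columns and `sequence`); at least two genera.
#' @param k word size, between 4 and 12.
#' @return a `kmer_classifier` with the log-probability matrix
#'   (`4^k` words x genera) and the genus -> lineage lookup.
#' @export
train_kmer_model <- function(refs, k = 8) {
  if (k < 4 || k > 12) stop("k must be between 4 and 12")
  genera <- unique(refs$genus)
  if (length(genera) < 2)
    stop("at least two genera are required to train a classifier")
  n_words <- 4^k
  logp <- matrix(NA_real_, nrow = n_words, ncol = length(genera),
                 dimnames = list(NULL, genera))
  lineage <- matrix(NA_character_, nrow = length(genera), ncol = 6,
                    dimnames = list(genera, RANKS))
  for (gi in seq_along(genera)) {
    members <- refs[refs$genus == genera[gi], , drop = FALSE]
    m <- nrow(members)
    counts <- numeric(n_words)
    for (s in members$sequence) {
      ids <- unique(kmer_ids(s, k))
      counts[ids + 1L] <- counts[ids + 1L] + 1
    }
    logp[, gi] <- log((counts + 0.5) / (m + 1))
    lineage[gi, ] <- unlist(members[1, RANKS])
  }
  structure(list(k = k, genera = genera, logp = logp, lineage = lineage),
            class = "kmer_classifier")
}

#' @export
print.kmer_classifier <- function(x, ...) {
  cat(sprintf("kmer_classifier: %d genera, k = %d\n", length(x$genera), x$k))
  invisible(x)
}

#' Classify a sequence with bootstrap confidence
#'
#' The genus call maximises the naive-Bayes log posterior over all k-mer
#' words of the query. Confidence is estimated by resampling `floor(W/8)`
#' of the query's `W` words with replacement `n_boot` times; the support at
#' each rank is the percentage of resamples whose winning genus falls in
#' the same clade as the full call at that rank, which makes supports
#' non-decreasing from genus towards domain.
#'
#' @param seq ungapped nucleotide string (gaps are removed first; windows
#'   containing N are skipped).
#' @param model a [train_kmer_model()] result.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed.
#' @return a `classification` with `labels` and `supports` (percent), both
#'   named by rank.
#' @export
classify_bootstrap <- function(seq, model, n_boot = 100, seed = 1) {
  stopifnot(inherits(model, "kmer_classifier"))
  if (n_boot < 1) stop("n_boot must be at least 1")
  tokens <- kmer_ids(gsub("-", "", seq, fixed = TRUE), model$k)
  if (length(tokens) < 1)
    stop("query has too few informative k-mers to classify")

  score <- colSums(model$logp[tokens + 1L, , drop = FALSE])
  full <- which.max(score)           # ties: first genus, deterministic
  full_lineage <- model$lineage[full, ]

  m <- max(1L, floor(length(tokens) / 8))
  winners <- with_seed(seed, {
    idm <- sample(tokens, m * n_boot, replace = TRUE)
    contrib <- model$logp[idm + 1L, , drop = FALSE]
    boot_scores <- rowsum(contrib, group = rep(seq_len(n_boot), each = m))
    max.col(boot_scores, ties.method = "first")
  })
  supports <- vapply(RANKS, function(r) {
    100 * mean(model$lineage[winners, r] == full_lineage[[r]])
  }, numeric(1))
  structure(list(labels = full_lineage, supports = supports,
                 genus_scores = score),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(paste0(names(x$labels), "=", x$labels, " (", round(x$supports), "%)",
             collapse = "; "), "\n")
  invisible(x)
}

# truncate a classification to its deepest rank passing the thresholds;
# deeper ranks become "unclassified"
.thresholded_lineage <- function(res, thr) {
  lab <- res$labels
  out <- setNames(rep("unclassified", 6), RANKS)
  for (r in RANKS) {
    if (.passes(res$supports[[r]], thr[[r]])) out[[r]] <- lab[[r]]
    else break
  }
  out
}

#' Select one consensus taxonomy per clone
#'
#' Each of the 5', 3' and (when available) full-length/concatenated
#' classifications is first truncated to its deepest rank passing the
#' bootstrap thresholds. Then:
#' * a strongly supported disagreement between any two inputs at family
#'   rank or above marks the clone a likely chimera
#'   (`status = "chimera_conflict"`, empty lineage);
#' * a disagreement confined to genus within a single family resolves to
#'   the majority genus when two of three inputs agree, and otherwise to
#'   `"unclassified"`;
#' * otherwise the deepest assignment among the inputs is accepted.
#'
#' @param res5,res3 classifications of the 5' and 3' reads.
#' @param resFull optional classification of the assembled or concatenated
#'   sequence; participates symmetrically.
#' @param thr [rank_thresholds()].
#' @param clone_id optional identifier carried into the result.
#' @return a `consensus_decision`: list with `clone_id`, `status`
#'   (`"accepted"` or `"chimera_conflict"`) and `lineage` (named ranks;
#'   empty for chimeras).
#' @export
consensus_taxonomy <- function(res5, res3, resFull = NULL,
                               thr = rank_thresholds(), clone_id = NA) {
  inputs <- Filter(Negate(is.null), list(res5, res3, resFull))
  stopifnot(length(inputs) >= 2)
  tl <- lapply(inputs, .thresholded_lineage, thr = thr)

  # chimera rule: strongly supported pairwise disagreement at family+
  high <- c("domain", "phylum", "class", "order", "family")
  for (r in high) {
    labs <- vapply(tl, `[[`, "", r)
    labs <- labs[labs != "unclassified"]
    if (length(unique(labs)) > 1) {
      return(structure(list(clone_id = clone_id,
                            status = "chimera_conflict",
                            conflict_rank = r,
                            lineage = setNames(character(0), character(0))),
                       class = "consensus_decision"))
    }
  }

  lineage <- setNames(rep("unclassified", 6), RANKS)
  for (r in high) {
    labs <- vapply(tl, `[[`, "", r)
    labs <- labs[labs != "unclassified"]
    if (length(labs)) lineage[[r]] <- labs[[1]] else break
  }
  if (lineage[["family"]] != "unclassified") {
    g <- vapply(tl, `[[`, "", "genus")
    g <- g[g != "unclassified"]
    if (length(g)) {
      tab <- sort(table(g), decreasing = TRUE)
      if (length(tab) == 1 || tab[1] * 2 > length(g))
        lineage[["genus"]] <- names(tab)[1]
      # even split stays "unclassified"
    }
  }
  structure(list(clone_id = clone_id, status = "accepted",
                 conflict_rank = NA_character_, lineage = lineage),
            class = "consensus_decision")
}

#' Partition endosymbionts and chloroplast sequences out of the community
#'
#' Intracellular endosymbionts (by default *Wolbachia* and *Spiroplasma*)
#' and chloroplast 16S are tallied separately from the free-living
#' community, matching the accounting of the original survey.
#'
#' @param decisions list of [consensus_taxonomy()] decisions.
#' @param endosymbionts lineage labels (any rank) diverted as endosymbionts.
#' @param chloroplast labels diverted as chloroplast.
#' @return list of decision lists: `community`, `endosymbiont`,
#'   `chloroplast`; counts are conserved.
#' @export
partition_special <- function(decisions,
                              endosymbionts = c("Wolbachia", "Spiroplasma"),
                              chloroplast = "Chloroplast") {
  matches <- function(d, labels) {
    length(d$lineage) > 0 &&
      any(tolower(d$lineage) %in% tolower(labels))
  }
  is_chl <- vapply(decisions, matches, logical(1), labels = chloroplast)
  is_end <- !is_chl &
    vapply(decisions, matches, logical(1), labels = endosymbionts)
  list(community = decisions[!is_chl & !is_end],
       endosymbiont = decisions[is_end],
       chloroplast = decisions[is_chl])
}

#' Per-clone taxonomy table
#'
#' @param decisions list of `consensus_decision`s.
#' @return data frame: clone_id, six rank columns, status.
#' @export
decision_table <- function(decisions) {
  do.call(rbind, lapply(decisions, function(d) {
    lin <- if (length(d$lineage)) d$lineage else
      setNames(rep(NA_character_, 6), RANKS)
    cbind(data.frame(clone_id = d$clone_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(lin), stringsAsFactors = FALSE),
          data.frame(status = d$status, stringsAsFactors = FALSE))
  }))
}
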