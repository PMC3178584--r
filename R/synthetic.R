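# Synthetic clone-library generator: reference taxonomies with rank-structured
# divergence, community profiles, and paired Sanger-style reads with known
# ground truth (parents, chimera breakpoints, overlap geometry).

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

.default_divergence <- c(
  taxon = 0.005, genus = 0.01, family = 0.03,
  order = 0.06, class = 0.10, phylum = 0.15
)

#' Generate a rank-structured 16S reference set
#'
#' Builds a balanced six-rank taxonomy (domain > phylum > class > order >
#' family > genus > taxon) and evolves one amplicon-length sequence per taxon
#' from a single random root by per-rank point substitution. The default
#' divergence ladder yields within-genus identity above 97%, so a 3% OTU
#' cutoff roughly recovers genera. Every sequence begins with the 27F primer
#' site and ends with the reverse complement of the 1492R site; primer sites
#' are never mutated.
#'
#' A level with a single child copies its parent unchanged, so
#' `n_genera = 1, taxa_per_genus = 1` returns the root sequence itself.
#'
#' @param n_genera number of genera (>= 1). Genera are packed two per family,
#'   families two per order, and so on up the ranks.
#' @param taxa_per_genus reference sequences per genus.
#' @param rank_divergence named fractions of interior positions substituted
#'   when a child lineage is spawned, from `taxon` (leaf sequences within a
#'   genus) up to `phylum`; must be strictly increasing and inside (0, 1).
#' @param amplicon_length total amplicon length including primer sites.
#' @param include_special also append divergent lineages for the intracellular
#'   endosymbionts *Wolbachia* and *Spiroplasma* and for chloroplast 16S, so
#'   the endosymbiont/chloroplast partitioning stage can be exercised.
#' @param seed integer seed; all randomness flows from it.
#' @return a `reference_set`: data frame with columns `taxon_id`, the six
#'   rank labels, and `sequence`; the generating root sequence is kept in
#'   `attr(, "root_sequence")`.
#' @export
build_reference_set <- function(n_genera, taxa_per_genus = 1,
                                rank_divergence = .default_divergence,
                                amplicon_length = 1450,
                                include_special = FALSE,
                                seed = 1) {
  stopifnot(n_genera >= 1, taxa_per_genus >= 1, amplicon_length >= 200)
  if (any(rank_divergence <= 0) || any(rank_divergence >= 1))
    stop("rank_divergence fractions must lie strictly inside (0, 1)")
  if (any(diff(rank_divergence) <= 0))
    stop("rank_divergence must increase strictly from taxon to phylum")

  with_seed(seed, {
    tail_rc <- revcomp(PRIMER_1492R)
    n_int <- amplicon_length - nchar(PRIMER_27F) - nchar(tail_rc)
    interior <- sample(1:4, n_int, replace = TRUE)
    root <- c(seq_to_codes(PRIMER_27F), interior, seq_to_codes(tail_rc))
    mut_pos <- seq(nchar(PRIMER_27F) + 1L, amplicon_length - nchar(tail_rc))

    # balanced packing: two children per node above the genus level
    n_fam <- ceiling(n_genera / 2)
    n_ord <- ceiling(n_fam / 2)
    n_cls <- ceiling(n_ord / 2)
    n_phy <- ceiling(n_cls / 2)
    parent_of <- function(i) ceiling(i / 2)
    spawn <- function(parents, n_children, frac, child_parent) {
      lapply(seq_len(n_children), function(i) {
        p <- parents[[child_parent(i)]]
        nsib <- sum(vapply(seq_len(n_children), child_parent, numeric(1)) ==
                      child_parent(i))
        if (nsib == 1) p else mutate_codes(p, frac, mut_pos)
      })
    }
    phy <- spawn(list(root), n_phy, rank_divergence[["phylum"]],
                 function(i) 1L)
    cls <- spawn(phy, n_cls, rank_divergence[["class"]], parent_of)
    ord <- spawn(cls, n_ord, rank_divergence[["order"]], parent_of)
    fam <- spawn(ord, n_fam, rank_divergence[["family"]], parent_of)
    gen <- spawn(fam, n_genera, rank_divergence[["genus"]], parent_of)

    rows <- list()
    for (g in seq_len(n_genera)) {
      f <- parent_of(g); o <- parent_of(f); cl <- parent_of(o)
      ph <- parent_of(cl)
      for (t in seq_len(taxa_per_genus)) {
        codes <- if (taxa_per_genus == 1) gen[[g]] else
          mutate_codes(gen[[g]], rank_divergence[["taxon"]], mut_pos)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_id = sprintf("G%02d_t%d", g, t),
          domain = "Bacteria",
          phylum = sprintf("Phylum_%d", ph),
          class = sprintf("Class_%d", cl),
          order = sprintf("Order_%d", o),
          family = sprintf("Family_%d", f),
          genus = sprintf("Genus_%d", g),
          sequence = codes_to_seq(codes),
          stringsAsFactors = FALSE
        )
      }
    }
    refs <- do.call(rbind, rows)

    if (include_special) {
      special <- list(
        list("Wolbachia_1", c("Bacteria", "Proteobacteria",
                              "Alphaproteobacteria", "Rickettsiales",
                              "Anaplasmataceae", "Wolbachia"), 0.18),
        list("Spiroplasma_1", c("Bacteria", "Tenericutes", "Mollicutes",
                                "Entomoplasmatales", "Spiroplasmataceae",
                                "Spiroplasma"), 0.20),
        list("Chloroplast_1", c("Bacteria", "Cyanobacteria", "Chloroplast",
                                "Chloroplast", "Chloroplast",
                                "Chloroplast"), 0.22)
      )
      for (sp in special) {
        codes <- mutate_codes(root, sp[[3]], mut_pos)
        refs <- rbind(refs, data.frame(
          taxon_id = sp[[1]],
          domain = sp[[2]][1], phylum = sp[[2]][2], class = sp[[2]][3],
          order = sp[[2]][4], family = sp[[2]][5], genus = sp[[2]][6],
          sequence = codes_to_seq(codes), stringsAsFactors = FALSE
        ))
      }
    }

    rownames(refs) <- NULL
    attr(refs, "root_sequence") <- codes_to_seq(root)
    attr(refs, "amplicon_length") <- amplicon_length
    class(refs) <- c("reference_set", "data.frame")
    refs
  })
}

#' Derive a distant outgroup sequence for tree rooting
#'
#' Returns a single highly divergent reference (a *Thermus*-like lineage)
#' evolved from the same root as `refs`, for use as the outgroup when
#' rooting the OTU tree.
#' @param refs a `reference_set`.
#' @param divergence substitution fraction from the root.
#' @param seed integer seed.
#' @return one-row `reference_set`-shaped data frame.
#' @export
outgroup_reference <- function(refs, divergence = 0.28, seed = 1) {
  root <- seq_to_codes(attr(refs, "root_sequence"))
  tail_rc <- revcomp(PRIMER_1492R)
  mut_pos <- seq(nchar(PRIMER_27F) + 1L, length(root) - nchar(tail_rc))
  with_seed(seed, {
    codes <- mutate_codes(root, divergence, mut_pos)
    data.frame(
      taxon_id = "OUTGROUP_Thermus", domain = "Bacteria",
      phylum = "Deinococcus-Thermus", class = "Deinococci",
      order = "Thermales", family = "Thermaceae", genus = "Thermus",
      sequence = codes_to_seq(codes), stringsAsFactors = FALSE
    )
  })
}

#' Define one community profile (a clone library's true composition)
#'
#' @param sample_id unique library identifier (e.g. `"LIB1"`).
#' @param weights named nonnegative numeric vector of relative abundances per
#'   reference `taxon_id`; normalised to sum to 1.
#' @param diet,species,environment metadata labels (environment is `"lab"`
#'   or `"wild"`).
#' @return a `community_profile` list.
#' @export
community_profile <- function(sample_id, weights, diet = "fruit",
                              species = "D_synthetica",
                              environment = "wild") {
  if (length(weights) == 0 || is.null(names(weights)))
    stop("weights must be a non-empty named vector")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(
    list(sample_id = sample_id, weights = weights / s,
         metadata = list(diet = diet, species = species,
                         environment = environment)),
    class = "community_profile"
  )
}

#' Simulate one clone library of paired Sanger reads
#'
#' Clone templates are drawn i.i.d. from the profile weights. A fraction
#' `chimera_rate` of clones are bimeric: the 5' portion of one parent is
#' joined to the 3' portion of a second, distinct parent at a breakpoint
#' uniform on the middle 80% of the amplicon, so both end-reads retain
#' parental signal. Each clone is sequenced from both ends; a fraction
#' `nonoverlap_frac` of clones get reads too short to overlap (the Sanger
#' regime in which roughly half of ~1450 bp amplicons cannot be assembled
#' from two ~700 nt reads). Per-base Phred qualities are drawn so that
#' `low_q_frac` of bases fall below Q15 (0.5% by default, the typical
#' residue of vector- and quality-trimmed Sanger reads); sequencing errors
#' are substitution-only.
#'
#' @param profile a [community_profile()].
#' @param refs a [build_reference_set()] result.
#' @param n_clones number of clones (>= 1).
#' @param read_len target read length in nt.
#' @param nonoverlap_frac fraction of clones whose reads must not overlap.
#' @param error_rate per-base substitution error probability.
#' @param chimera_rate fraction of clones that are bimeric.
#' @param low_q_frac fraction of bases assigned quality below 15.
#' @param indel_rate per-base insertion/deletion probability (default 0:
#'   substitution-only error keeps alignment behaviour interpretable).
#' @param seed integer seed.
#' @return a `clone_library`: list with `clones` (each holding `clone_id`,
#'   `fwd_read`, `fwd_qual`, `rev_read`, `rev_qual`, `overlap`,
#'   `parent_ids`, `breakpoint`, `is_chimera`), plus the profile and
#'   parameters. `rev_read` is reverse-complement oriented.
#' @export
sample_clone_library <- function(profile, refs, n_clones, read_len = 700,
                                 nonoverlap_frac = 0.5, error_rate = 0.002,
                                 chimera_rate = 0.02, low_q_frac = 0.005,
                                 indel_rate = 0, seed = 1) {
  stopifnot(inherits(profile, "community_profile"), n_clones >= 1)
  w <- profile$weights
  missing_ids <- setdiff(names(w), refs$taxon_id)
  if (length(missing_ids))
    stop("profile names absent from reference set: ",
         paste(missing_ids, collapse = ", "))
  seqs <- setNames(refs$sequence, refs$taxon_id)
  L <- unique(nchar(seqs[names(w)]))
  if (length(L) != 1) stop("reference amplicons must share one length")
  if (read_len >= L) stop("read_len must be below the amplicon length")

  with_seed(seed, {
    clones <- vector("list", n_clones)
    bp_lo <- ceiling(0.1 * L); bp_hi <- floor(0.9 * L)
    for (i in seq_len(n_clones)) {
      p1 <- sample(names(w), 1, prob = w)
      is_chi <- length(w) >= 2 && runif(1) < chimera_rate
      if (is_chi) {
        others <- setdiff(names(w), p1)
        p2 <- if (length(others) == 1) others else
          sample(others, 1, prob = w[others] / sum(w[others]))
        bp <- sample(bp_lo:bp_hi, 1)
        amplicon <- paste0(substr(seqs[[p1]], 1, bp),
                           substr(seqs[[p2]], bp + 1, L))
        parents <- c(p1, p2)
      } else {
        amplicon <- seqs[[p1]]
        parents <- p1
        bp <- NA_integer_
      }

      nonov <- runif(1) < nonoverlap_frac
      if (nonov) {
        rl <- if (2 * read_len < L - 20) read_len else floor((L - 50) / 2)
      } else {
        rl <- max(read_len, ceiling((L + 60) / 2))
        rl <- min(rl, L - 1)
      }

      sequencer <- function(region) {
        codes <- seq_to_codes(region)
        nerr <- rbinom(1, length(codes), error_rate)
        if (nerr > 0) {
          at <- sample(length(codes), nerr)
          for (j in at) codes[j] <- sample(setdiff(1:4, codes[j]), 1)
        }
        if (indel_rate > 0) {
          nind <- rbinom(1, length(codes), indel_rate)
          if (nind > 0) {
            at <- sort(sample(length(codes), nind), decreasing = TRUE)
            for (j in at) {
              codes <- if (runif(1) < 0.5) codes[-j] else
                append(codes, sample(1:4, 1), after = j)
            }
          }
        }
        qual <- ifelse(runif(length(codes)) < low_q_frac,
                       sample(2:14, length(codes), replace = TRUE),
                       sample(25:60, length(codes), replace = TRUE))
        list(seq = codes_to_seq(codes), qual = as.integer(qual))
      }
      f <- sequencer(substr(amplicon, 1, rl))
      r0 <- sequencer(substr(amplicon, L - rl + 1, L))

      clones[[i]] <- list(
        clone_id = sprintf("%s_c%04d", profile$sample_id, i),
        library_id = profile$sample_id,
        fwd_read = f$seq, fwd_qual = f$qual,
        rev_read = revcomp(r0$seq), rev_qual = rev(r0$qual),
        overlap = !nonov, parent_ids = parents,
        breakpoint = bp, is_chimera = is_chi
      )
    }
    structure(
      list(clones = clones, profile = profile,
           params = list(n_clones = n_clones, read_len = read_len,
                         nonoverlap_frac = nonoverlap_frac,
                         error_rate = error_rate,
                         chimera_rate = chimera_rate,
                         low_q_frac = low_q_frac, seed = seed)),
      class = "clone_library"
    )
  })
}

#' Ground-truth table of a simulated clone library
#'
#' @param lib a `clone_library`.
#' @return data frame with one row per clone: parents, breakpoint and flags.
#' @export
clone_truth <- function(lib) {
  stopifnot(inherits(lib, "clone_library"))
  do.call(rbind, lapply(lib$clones, function(cl) data.frame(
    clone_id = cl$clone_id, library_id = cl$library_id,
    parent_1 = cl$parent_ids[1],
    parent_2 = if (length(cl$parent_ids) > 1) cl$parent_ids[2] else NA,
    breakpoint = cl$breakpoint, is_chimera = cl$is_chimera,
    overlap = cl$overlap, stringsAsFactors = FALSE
  )))
}

#' Simulate a complete multi-library study
#'
#' Builds a reference set, an outgroup, and one clone library per sample.
#' Each library is dominated by a single family (weight `dominant_weight`),
#' mirroring the empirical pattern in which a handful of bacterial families
#' (Enterobacteriaceae-, Acetobacteraceae- or Lactobacillales-like lineages)
#' dominate any one host sample; the remainder is spread over all other
#' community taxa with random jitter. When `include_special` is set, every
#' library also carries a *Wolbachia* endosymbiont spike and a trace of
#' chloroplast sequence.
#'
#' @param n_libraries number of clone libraries.
#' @param clones_per_library clones simulated per library.
#' @param n_genera,taxa_per_genus passed to [build_reference_set()].
#' @param dominant_weight relative abundance of each library's dominant
#'   family.
#' @param include_special include endosymbiont/chloroplast lineages.
#' @param endosymbiont_frac,chloroplast_frac spike weights (only used with
#'   `include_special`).
#' @param diets recycled diet labels over libraries.
#' @param seed master seed; library seeds are derived from it.
#' @param ... further arguments passed to [sample_clone_library()].
#' @return list with `refs`, `outgroup`, `profiles`, `libraries`.
#' @export
simulate_study <- function(n_libraries = 3, clones_per_library = 100,
                           n_genera = 8, taxa_per_genus = 2,
                           dominant_weight = 0.6,
                           include_special = FALSE,
                           endosymbiont_frac = 0.05,
                           chloroplast_frac = 0.01,
                           diets = c("fruit", "flower"),
                           seed = 1, ...) {
  refs <- build_reference_set(n_genera, taxa_per_genus,
                              include_special = include_special,
                              seed = child_seed(seed, 1))
  og <- outgroup_reference(refs, seed = child_seed(seed, 2))
  special_fams <- c("Anaplasmataceae", "Spiroplasmataceae", "Chloroplast")
  comm <- refs[!(refs$family %in% special_fams), , drop = FALSE]
  fams <- unique(comm$family)

  profiles <- vector("list", n_libraries)
  libraries <- vector("list", n_libraries)
  for (i in seq_len(n_libraries)) {
    lib_id <- sprintf("LIB%d", i)
    dom <- fams[((i - 1) %% length(fams)) + 1]
    spike <- if (include_special) endosymbiont_frac + chloroplast_frac else 0
    w <- setNames(numeric(nrow(comm)), comm$taxon_id)
    in_dom <- comm$family == dom
    w[in_dom] <- dominant_weight / sum(in_dom)
    rest <- with_seed(child_seed(seed, 100 + i),
                      runif(sum(!in_dom), 0.5, 1.5))
    w[!in_dom] <- (1 - dominant_weight - spike) * rest / sum(rest)
    if (include_special) {
      w <- c(w,
             setNames(endosymbiont_frac,
                      refs$taxon_id[refs$genus == "Wolbachia"][1]),
             setNames(chloroplast_frac,
                      refs$taxon_id[refs$family == "Chloroplast"][1]))
    }
    profiles[[i]] <- community_profile(
      lib_id, w, diet = diets[((i - 1) %% length(diets)) + 1],
      species = sprintf("D_synthetica_%d", i), environment = "wild"
    )
    libraries[[i]] <- sample_clone_library(
      profiles[[i]], refs, clones_per_library,
      seed = child_seed(seed, 200 + i), ...
    )
  }
  list(refs = refs, outgroup = og, profiles = profiles,
       libraries = libraries, seed = seed)
}

#' Write a clone library as FASTA plus a parallel quality file
#'
#' Forward and reverse reads are written as `<clone_id>/f` and
#' `<clone_id>/r`; the `.qual` file holds space-separated Phred scores under
#' the same headers. The ground-truth table is written as TSV alongside.
#'
#' @param lib a `clone_library`.
#' @param fasta,qual,truth output paths (`NULL` to skip a file).
#' @return invisibly, the paths written.
#' @export
write_clone_library <- function(lib, fasta, qual = NULL, truth = NULL) {
  stopifnot(inherits(lib, "clone_library"))
  ids <- unlist(lapply(lib$clones,
                       function(cl) paste0(cl$clone_id, c("/f", "/r"))))
  seqs <- unlist(lapply(lib$clones, function(cl) c(cl$fwd_read, cl$rev_read)))
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(seqs), ids), fasta)
  if (!is.null(qual)) {
    con <- file(qual, "w"); on.exit(close(con))
    for (cl in lib$clones) {
      writeLines(c(paste0(">", cl$clone_id, "/f"),
                   paste(cl$fwd_qual, collapse = " "),
                   paste0(">", cl$clone_id, "/r"),
                   paste(cl$rev_qual, collapse = " ")), con)
    }
  }
  if (!is.null(truth))
    write.table(clone_truth(lib), truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(fasta = fasta, qual = qual, truth = truth))
}
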