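# End-to-end orchestration: config validation, the staged pipeline with a
# filtering ledger, per-rank composition tables, and TSV/Newick/FASTA output.

#' Build and validate a study configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#' Simulation settings describe the synthetic study; thresholds mirror the
#' published workflow (Q15 masking, >80% gap-column trimming, 300 nt length
#' filter, 0.03 OTU cutoff, the bootstrap threshold ladder, and a minimum
#' retained-library size of 26 below which a library is dropped whole).
#'
#' @param seed mandatory integer seed; every stage derives its randomness
#'   from it.
#' @param n_libraries,clones_per_library,n_genera,taxa_per_genus,include_special
#'   simulation settings (see [simulate_study()]).
#' @param q_min quality-masking threshold.
#' @param min_overlap,min_identity pair-assembly acceptance.
#' @param max_gap_frac gap-column trim threshold.
#' @param min_nongap post-trim length filter.
#' @param cutoff OTU distance cutoff.
#' @param n_boot bootstrap resamples per classification.
#' @param n_perm UniFrac permutations.
#' @param min_library_size libraries retained only at or above this size.
#' @param grouping metadata variable for UniFrac bins (`"diet"`,
#'   `"environment"` or `"species"`).
#' @param out_dir optional output directory; when set, all tables, trees
#'   and the ledger are written there.
#' @param ... further arguments passed to [sample_clone_library()] via
#'   [simulate_study()] (e.g. `error_rate`, `chimera_rate`).
#' @return a validated `study_config` list.
#' @export
study_config <- function(seed,
                         n_libraries = 3, clones_per_library = 100,
                         n_genera = 8, taxa_per_genus = 2,
                         include_special = FALSE,
                         q_min = 15, min_overlap = 30, min_identity = 0.90,
                         max_gap_frac = 0.80, min_nongap = 300,
                         cutoff = 0.03, n_boot = 100, n_perm = 1000,
                         min_library_size = 26,
                         grouping = "diet", out_dir = NULL, ...) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(q_min >= 0, min_overlap >= 1,
            min_identity > 0, min_identity <= 1,
            max_gap_frac > 0, max_gap_frac <= 1,
            min_nongap >= 0, cutoff >= 0, cutoff <= 1,
            n_boot >= 1, n_perm >= 1, min_library_size >= 0)
  grouping <- match.arg(grouping, c("diet", "environment", "species"))
  structure(
    c(list(seed = as.integer(seed), n_libraries = n_libraries,
           clones_per_library = clones_per_library, n_genera = n_genera,
           taxa_per_genus = taxa_per_genus,
           include_special = include_special, q_min = q_min,
           min_overlap = min_overlap, min_identity = min_identity,
           max_gap_frac = max_gap_frac, min_nongap = min_nongap,
           cutoff = cutoff, n_boot = n_boot, n_perm = n_perm,
           min_library_size = min_library_size, grouping = grouping,
           out_dir = out_dir),
      list(...)),
    class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys match [study_config()] arguments.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

# ledger helpers: every filtering stage appends one record and the next
# stage must start from the previous stage's retained count
.ledger_new <- function() {
  data.frame(stage = character(0), input = integer(0),
             removed = integer(0), retained = integer(0),
             reason = character(0), stringsAsFactors = FALSE)
}
.ledger_add <- function(ledger, stage, input, removed, reason) {
  input <- as.integer(input); removed <- as.integer(removed)
  rbind(ledger, data.frame(stage = stage, input = input, removed = removed,
                           retained = input - removed, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Run the whole clone-library pipeline
#'
#' Simulates (or accepts) a multi-library study, then: masks low-quality
#' bases; assembles or gap-concatenates each read pair in reference
#' coordinates; trims high-gap columns and drops short rows; classifies the
#' 5', 3' and full-length sequences and selects a consensus taxonomy,
#' excluding taxonomy-conflict chimeras; diverts endosymbionts and
#' chloroplasts; drops libraries that end up below the minimum size;
#' clusters the survivors into OTUs at the distance cutoff; and computes
#' diversity summaries, beta-diversity, the representative tree, UniFrac
#' group tests and ordination, and per-rank composition tables. Every
#' filtering step is recorded in a conservation-checked ledger.
#'
#' @param cfg a [study_config()].
#' @param study optional pre-built study (as from [simulate_study()]); by
#'   default one is simulated from `cfg`.
#' @return a `pipeline_result` list: `ledger`, `decisions`, `alignment`,
#'   `distance`, `partition`, `otu_table`, `diversity`, `beta`,
#'   `rarefaction`, `tree`, `unifrac`, `unifrac_test`, `ordination`,
#'   `composition`, `truth`, `config`.
#' @export
run_pipeline <- function(cfg, study = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(study)) {
    sim_args <- cfg[intersect(names(cfg),
                              names(formals(simulate_study)))]
    extra <- cfg[intersect(names(cfg),
                           setdiff(names(formals(sample_clone_library)),
                                   c("profile", "refs", "n_clones", "seed")))]
    study <- do.call(simulate_study, c(sim_args, extra))
  }
  ledger <- .ledger_new()
  clones <- unlist(lapply(study$libraries, `[[`, "clones"),
                   recursive = FALSE)
  n0 <- length(clones)
  if (n0 == 0)
    stop("stage preprocess: 0 input clones (nothing to analyse)")
  message(sprintf("pipeline: %d clones in %d libraries",
                  n0, length(study$libraries)))

  ref_aln <- as_reference_alignment(study$refs)
  model <- train_kmer_model(study$refs)

  ## -- preprocess + classify every clone ---------------------------------
  rows <- character(n0); origins <- character(n0)
  seq_ids <- character(n0); lib_ids <- character(n0)
  decisions <- vector("list", n0)
  for (i in seq_len(n0)) {
    cl <- clones[[i]]
    f <- mask_low_quality(cl$fwd_read, cl$fwd_qual, cfg$q_min)
    r <- mask_low_quality(cl$rev_read, cl$rev_qual, cfg$q_min)
    r_fwd <- revcomp(r)
    mg <- merge_pair(f, r, cl$fwd_qual, cl$rev_qual,
                     min_overlap = cfg$min_overlap,
                     min_identity = cfg$min_identity)
    if (mg$assembled) {
      al <- align_to_reference(mg$seq, ref_aln)
      rows[i] <- al$row; origins[i] <- "assembled"
      full_seq <- mg$seq
    } else {
      a5 <- align_to_reference(f, ref_aln)
      a3 <- align_to_reference(r_fwd, ref_aln)
      cc <- tryCatch(concatenate_nonoverlapping(a5$row, a3$row),
                     error = function(e) NULL)
      if (is.null(cc)) {
        # slight aligned overlap despite failed assembly: give the forward
        # read priority over the clashing columns
        f_ch <- strsplit(a5$row, "", fixed = TRUE)[[1]]
        r_ch <- strsplit(a3$row, "", fixed = TRUE)[[1]]
        out <- ifelse(f_ch != "-", f_ch, r_ch)
        rows[i] <- paste(out, collapse = "")
      } else rows[i] <- cc$row
      origins[i] <- "concatenated"
      full_seq <- gsub("-", "", rows[i], fixed = TRUE)
    }
    res5 <- classify_bootstrap(f, model, n_boot = cfg$n_boot,
                               seed = child_seed(cfg$seed, 1000 + i))
    res3 <- classify_bootstrap(r_fwd, model, n_boot = cfg$n_boot,
                               seed = child_seed(cfg$seed, 2000 + i))
    resF <- classify_bootstrap(full_seq, model, n_boot = cfg$n_boot,
                               seed = child_seed(cfg$seed, 3000 + i))
    decisions[[i]] <- consensus_taxonomy(res5, res3, resF,
                                         clone_id = cl$clone_id)
    seq_ids[i] <- cl$clone_id; lib_ids[i] <- cl$library_id
  }
  names(decisions) <- seq_ids
  aln <- alignment_matrix(seq_ids, rows, lib_ids, origins)
  ledger <- .ledger_add(ledger, "preprocess", n0, 0,
                        "paired reads masked, assembled or concatenated")

  ## -- trim and length-filter -------------------------------------------
  aln <- trim_gap_columns(aln, cfg$max_gap_frac)
  fs <- filter_short(aln, cfg$min_nongap)
  aln <- fs$alignment
  ledger <- .ledger_add(ledger, "length_filter", n0, nrow(fs$removed),
                        sprintf("fewer than %d non-gap characters after trimming",
                                cfg$min_nongap))

  ## -- chimera exclusion and special-lineage partitioning ----------------
  kept_ids <- aln$seq_id
  dec_kept <- decisions[kept_ids]
  chim <- vapply(dec_kept, function(d) d$status == "chimera_conflict",
                 logical(1))
  ledger <- .ledger_add(ledger, "chimera_conflict", length(kept_ids),
                        sum(chim), "conflicting 5'/3' taxonomy at family rank or above")
  kept_ids <- kept_ids[!chim]
  part <- partition_special(decisions[kept_ids])
  n_in <- length(kept_ids)
  ledger <- .ledger_add(ledger, "chloroplast", n_in,
                        length(part$chloroplast), "chloroplast 16S diverted")
  ledger <- .ledger_add(ledger, "endosymbiont",
                        n_in - length(part$chloroplast),
                        length(part$endosymbiont),
                        "intracellular endosymbionts diverted")
  kept_ids <- vapply(part$community, `[[`, "", "clone_id")

  ## -- drop undersized libraries ----------------------------------------
  lib_of <- setNames(lib_ids, seq_ids)
  sizes <- table(lib_of[kept_ids])
  small <- names(sizes)[sizes < cfg$min_library_size]
  n_in <- length(kept_ids)
  kept_ids <- kept_ids[!(lib_of[kept_ids] %in% small)]
  ledger <- .ledger_add(ledger, "small_libraries", n_in,
                        n_in - length(kept_ids),
                        sprintf("libraries below %d retained sequences removed (%s)",
                                cfg$min_library_size,
                                if (length(small)) paste(small, collapse = ",")
                                else "none"))
  if (length(kept_ids) < 2)
    stop("stage otu_cluster: fewer than 2 sequences survive filtering")

  keep <- aln$seq_id %in% kept_ids
  aln_final <- alignment_matrix(aln$seq_id[keep], aln$row[keep],
                                aln$library_id[keep], aln$origin[keep],
                                col_index = aln$col_index,
                                removed_columns = aln$removed_columns)

  ## -- OTU clustering ----------------------------------------------------
  dm <- pairwise_distance(aln_final)
  part_otu <- average_neighbor_cluster(dm, cfg$cutoff)
  rep_first <- build_otu_table(part_otu, lib_of, dm = dm)
  rep_seqs <- setNames(
    gsub("-", "", aln_final$row[match(unname(rep_first$representative),
                                      aln_final$seq_id)], fixed = TRUE),
    unname(rep_first$representative))
  otab <- relabel_otu_table(rep_first, decisions, rep_seqs, study$refs)
  message(sprintf("pipeline: %d sequences fell into %d OTUs at cutoff %.2f",
                  sum(otab$counts), nrow(otab$counts), cfg$cutoff))

  ## -- diversity ---------------------------------------------------------
  div <- diversity_summary(otab)
  beta <- beta_diversity_table(otab)
  rare <- lapply(setNames(nm = colnames(otab$counts)), function(l) {
    rarefaction(otab$counts[, l])
  })

  ## -- tree, UniFrac, ordination ----------------------------------------
  og_row <- align_to_reference(study$outgroup$sequence[1], ref_aln)$row
  og_row <- paste(strsplit(og_row, "", fixed = TRUE)[[1]][aln$col_index],
                  collapse = "")
  rep_ids <- unname(otab$representative)
  rep_rows <- aln_final$row[match(rep_ids, aln_final$seq_id)]
  tree_aln <- alignment_matrix(c(rep_ids, "OUTGROUP"),
                               c(rep_rows, og_row))
  tree <- NULL; uf <- NULL; uftest <- NULL; ord <- NULL
  if (length(rep_ids) >= 2) {
    dm_tree <- pairwise_distance(tree_aln)
    tree <- nj_tree(dm_tree, "OUTGROUP")
    memb <- otu_membership(otab)
    uf <- unifrac_matrix(tree, memb)
    meta <- vapply(study$profiles,
                   function(p) p$metadata[[cfg$grouping]], "")
    names(meta) <- vapply(study$profiles, `[[`, "", "sample_id")
    meta <- meta[colnames(memb)]
    if (length(unique(meta)) >= 2) {
      uftest <- unifrac_permutation_test(tree, memb, meta,
                                         n_perm = cfg$n_perm,
                                         seed = child_seed(cfg$seed, 7))
    }
    if (ncol(uf) >= 2) ord <- pcoa(uf)
  }

  ## -- composition -------------------------------------------------------
  comp <- composition_table(otab, "family")

  res <- structure(list(
    ledger = ledger, decisions = decisions, alignment = aln_final,
    distance = dm, partition = part, otu_table = otab, diversity = div,
    beta = beta, rarefaction = rare, tree = tree, unifrac = uf,
    unifrac_test = uftest, ordination = ord, composition = comp,
    truth = do.call(rbind, lapply(study$libraries, clone_truth)),
    study = study, config = cfg
  ), class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("clone-library pipeline result\n")
  print(x$ledger)
  print(x$otu_table)
  invisible(x)
}

#' Composition-by-rank proportions
#'
#' Proportion of sequences per taxon label at a rank, within each group of
#' libraries (or per library when no grouping is given). Rows sum to 1.
#'
#' @param table a relabeled [build_otu_table()] result.
#' @param rank one of phylum, class, order, family, genus.
#' @param group_by optional named vector library -> group label.
#' @return matrix groups x rank labels of proportions.
#' @export
composition_table <- function(table, rank, group_by = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% setdiff(RANKS, "domain"))
    stop("unknown rank '", rank, "'")
  if (is.null(table$lineage))
    stop("OTU table has no lineage; run relabel_otu_table() first")
  labels <- table$lineage[[rank]]
  libs <- colnames(table$counts)
  groups <- if (is.null(group_by)) setNames(libs, libs) else group_by[libs]
  glev <- sort(unique(unname(groups)))
  llev <- sort(unique(labels))
  out <- matrix(0, length(glev), length(llev),
                dimnames = list(glev, llev))
  for (g in glev) {
    cnt <- rowSums(table$counts[, libs[groups == g], drop = FALSE])
    tot <- tapply(cnt, labels, sum)
    out[g, names(tot)] <- tot / sum(cnt)
  }
  out
}

#' Write all pipeline artifacts to a directory
#'
#' TSV tables (ledger, taxonomy decisions, OTU table, diversity, beta,
#' rarefaction, UniFrac matrix and tests, ordination, composition), the
#' trimmed alignment as FASTA, the representative tree as Newick and the
#' membership as a UniFrac environment file.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(res$ledger, "ledger.tsv")
  w(decision_table(res$decisions), "taxonomy.tsv")
  write_otu_table(res$otu_table, file.path(dir, "otu_table.tsv"))
  w(res$diversity, "diversity.tsv")
  w(res$beta, "beta_diversity.tsv")
  rare <- do.call(rbind, lapply(names(res$rarefaction), function(l) {
    cbind(library = l, res$rarefaction[[l]])
  }))
  w(rare, "rarefaction.tsv")
  write_alignment_fasta(res$alignment, file.path(dir, "alignment.fasta"))
  if (!is.null(res$tree))
    ape::write.tree(res$tree, file.path(dir, "representatives.nwk"))
  if (!is.null(res$unifrac))
    write.table(res$unifrac, file.path(dir, "unifrac.tsv"),
                sep = "\t", quote = FALSE)
  if (!is.null(res$unifrac_test)) w(res$unifrac_test, "unifrac_tests.tsv")
  if (!is.null(res$ordination)) {
    write.table(res$ordination$coordinates, file.path(dir, "pcoa.tsv"),
                sep = "\t", quote = FALSE)
  }
  write.table(res$composition, file.path(dir, "composition_family.tsv"),
              sep = "\t", quote = FALSE)
  if (!is.null(res$otu_table))
    write_unifrac_env(otu_membership(res$otu_table),
                      file.path(dir, "unifrac_env.tsv"))
  invisible(dir)
}

#' Headline counts of the published survey
#'
#' The printed dataset summary of the wild *Drosophila* clone-library
#' survey this package reimplements: 3243 retained near-full-length 16S
#' sequences across 39 libraries, clustering into 139 OTUs at the 3%
#' cutoff. Useful for closed-form arithmetic checks such as the mean OTU
#' abundance (sequences per OTU) and the mean library size.
#'
#' @return list with `total_sequences`, `n_otus`, `n_libraries`.
#' @export
survey_summary <- function() {
  list(total_sequences = 3243L, n_otus = 139L, n_libraries = 39L)
}
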