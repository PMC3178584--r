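# Classifier training, bootstrap supports, the consensus decision procedure
# and special-lineage partitioning.

test_that("training validates its inputs and is deterministic", {
  refs <- fixture_refs()
  expect_error(train_kmer_model(refs[refs$genus == "Genus_1", ]),
               "two genera")
  expect_error(train_kmer_model(refs, k = 3), "between 4 and 12")
  expect_error(train_kmer_model(refs, k = 13), "between 4 and 12")
  m1 <- train_kmer_model(refs)
  m2 <- train_kmer_model(refs)
  expect_identical(m1$logp, m2$logp)
})

test_that("training sequences classify to their own genus with high support", {
  refs <- fixture_refs()
  m <- train_kmer_model(refs)
  for (i in c(1, 5, 9, 13)) {
    res <- classify_bootstrap(refs$sequence[i], m, seed = 100 + i)
    expect_identical(unname(res$labels[["genus"]]), refs$genus[i])
    expect_gte(res$supports[["genus"]], 95)
    # exhaustive check: the called genus attains the maximum posterior
    expect_identical(names(which.max(res$genus_scores)), refs$genus[i])
  }
})

test_that("bootstrap supports are monotone toward the root and seeded", {
  refs <- fixture_refs()
  m <- train_kmer_model(refs)
  set.seed(77)
  for (i in sample(nrow(refs), 4)) {
    # add noise so supports are not trivially 100 everywhere
    ch <- strsplit(refs$sequence[i], "", fixed = TRUE)[[1]]
    at <- sample(length(ch), 40)
    ch[at] <- sample(c("A", "C", "G", "T"), 40, TRUE)
    q <- paste(ch, collapse = "")
    r1 <- classify_bootstrap(q, m, seed = 5)
    r2 <- classify_bootstrap(q, m, seed = 5)
    expect_identical(r1$supports, r2$supports)
    s <- r1$supports[ranks]   # domain ... genus
    expect_true(all(diff(s) <= 1e-9))
  }
  expect_error(classify_bootstrap(refs$sequence[1], m, n_boot = 0),
               "at least 1")
  expect_error(classify_bootstrap("ACGT", m), "too few")
})

test_that("the consensus decision table matches the published rules", {
  thr <- rank_thresholds()
  full <- function(...) mk_classification(...)

  # agreement with full support
  d <- consensus_taxonomy(full(), full())
  expect_identical(d$status, "accepted")
  expect_identical(unname(d$lineage[["genus"]]), "Genus_1")

  # strongly supported family conflict -> chimera
  d <- consensus_taxonomy(
    full(family = "Enterobacteriaceae", genus = "Serratia",
         supports = c(100, 100, 100, 100, 99, 99)),
    full(family = "Lactobacillaceae", genus = "Lactobacillus",
         supports = c(100, 100, 100, 100, 99, 99)))
  expect_identical(d$status, "chimera_conflict")
  expect_length(d$lineage, 0)

  # order-level conflict is also a chimera
  d <- consensus_taxonomy(full(order = "Order_1"), full(order = "Order_2"))
  expect_identical(d$status, "chimera_conflict")

  # same family, strongly supported different genera -> unclassified genus
  d <- consensus_taxonomy(full(genus = "GenA", supports = c(100, 100, 100, 100, 100, 80)),
                          full(genus = "GenB", supports = c(100, 100, 100, 100, 100, 82)))
  expect_identical(d$status, "accepted")
  expect_identical(unname(d$lineage[["family"]]), "Family_1")
  expect_identical(unname(d$lineage[["genus"]]), "unclassified")

  # genus support of exactly 75 is not accepted (strict >), family survives
  d <- consensus_taxonomy(full(supports = c(100, 100, 100, 100, 90, 75)),
                          full(supports = c(100, 100, 100, 100, 90, 75)))
  expect_identical(unname(d$lineage[["genus"]]), "unclassified")
  expect_identical(unname(d$lineage[["family"]]), "Family_1")

  # family support of exactly 80 fails; conflict below the accepted depth
  # cannot trigger a chimera call
  d <- consensus_taxonomy(full(family = "FamA", supports = c(100, 100, 100, 100, 80, 60)),
                          full(family = "FamB", supports = c(100, 100, 100, 100, 80, 60)))
  expect_identical(d$status, "accepted")
  expect_identical(unname(d$lineage[["family"]]), "unclassified")
  expect_identical(unname(d$lineage[["order"]]), "Order_1")

  # weakly supported family dissent does not override a strong assignment
  d <- consensus_taxonomy(full(family = "FamA", supports = c(100, 100, 100, 100, 99, 99)),
                          full(family = "FamB", supports = c(100, 100, 100, 100, 79, 50)))
  expect_identical(d$status, "accepted")
  expect_identical(unname(d$lineage[["family"]]), "FamA")

  # 2-of-3 genus majority wins below family rank
  d <- consensus_taxonomy(full(genus = "GenA"), full(genus = "GenA"),
                          full(genus = "GenB"))
  expect_identical(unname(d$lineage[["genus"]]), "GenA")

  # class threshold demands exactly 100
  d <- consensus_taxonomy(full(supports = c(100, 100, 99, 99, 90, 80)),
                          full(supports = c(100, 100, 99, 99, 90, 80)))
  expect_identical(unname(d$lineage[["class"]]), "unclassified")
  expect_identical(unname(d$lineage[["phylum"]]), "Phylum_1")
})

test_that("every agreement/conflict/support cell yields exactly one status", {
  thr <- rank_thresholds()
  statuses <- c()
  for (fam_b in c("Family_1", "Family_2")) {
    for (gen_b in c("Genus_1", "Genus_2")) {
      for (fam_sup in c(79, 81, 100)) {
        for (gen_sup in c(70, 76, 100)) {
          a <- mk_classification()
          b <- mk_classification(family = fam_b, genus = gen_b,
                                 supports = c(100, 100, 100, 100,
                                              fam_sup, gen_sup))
          d <- consensus_taxonomy(a, b, thr = thr)
          expect_true(d$status %in% c("accepted", "chimera_conflict"))
          # chimera iff the family labels differ AND the divergent family
          # passed its threshold
          expect_identical(d$status == "chimera_conflict",
                           fam_b != "Family_1" && fam_sup > 80)
          statuses <- c(statuses, d$status)
        }
      }
    }
  }
  expect_identical(length(statuses), 36L)
})

test_that("cross-family chimeras are flagged; within-genus chimeras are not", {
  refs <- build_reference_set(8, 2, seed = 31)
  m <- train_kmer_model(refs)
  seqs <- setNames(refs$sequence, refs$taxon_id)
  L <- nchar(seqs[[1]])
  chimera_of <- function(p1, p2, bp) {
    paste0(substr(seqs[[p1]], 1, bp), substr(seqs[[p2]], bp + 1, L))
  }
  classify_ends <- function(s, seed) {
    f <- substr(s, 1, 700)
    r <- substr(s, L - 699, L)
    consensus_taxonomy(classify_bootstrap(f, m, seed = seed),
                       classify_bootstrap(r, m, seed = seed + 1))
  }
  # parents from different families (Genus_1 vs Genus_5 live in different
  # orders under the balanced packing)
  n_flag <- 0
  for (bp in c(500, 725, 950)) {
    d <- classify_ends(chimera_of("G01_t1", "G05_t1", bp), bp)
    n_flag <- n_flag + (d$status == "chimera_conflict")
  }
  expect_gte(n_flag, 2)
  # parents within one genus: correctly NOT flagged
  d <- classify_ends(chimera_of("G01_t1", "G01_t2", 725), 99)
  expect_identical(d$status, "accepted")
})

test_that("genus recall on error-free reads exceeds 95%", {
  refs <- build_reference_set(6, 2, seed = 51)
  m <- train_kmer_model(refs)
  prof <- community_profile("R", setNames(rep(1, nrow(refs)), refs$taxon_id))
  lib <- sample_clone_library(prof, refs, 40, error_rate = 0, low_q_frac = 0,
                              chimera_rate = 0, seed = 52)
  genus_of <- setNames(refs$genus, refs$taxon_id)
  hits <- vapply(lib$clones, function(cl) {
    d <- consensus_taxonomy(
      classify_bootstrap(cl$fwd_read, m, seed = 1),
      classify_bootstrap(revcomp(cl$rev_read), m, seed = 2))
    identical(unname(d$lineage[["genus"]]), unname(genus_of[cl$parent_ids[1]]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("special lineages are diverted with counts conserved", {
  mk_dec <- function(genus, class = "Class_1") {
    structure(list(clone_id = genus, status = "accepted",
                   lineage = c(domain = "Bacteria", phylum = "P",
                               class = class, order = "O", family = "F",
                               genus = genus)),
              class = "consensus_decision")
  }
  decs <- c(lapply(sprintf("g%d", 1:7), mk_dec),
            lapply(rep("Wolbachia", 3), mk_dec))
  p <- partition_special(decs)
  expect_length(p$community, 7)
  expect_length(p$endosymbiont, 3)
  expect_length(p$chloroplast, 0)
  expect_identical(length(p$community) + length(p$endosymbiont) +
                     length(p$chloroplast), length(decs))
  # chloroplast matches at any rank, case-insensitively
  p2 <- partition_special(list(mk_dec("x", class = "chloroplast")))
  expect_length(p2$chloroplast, 1)
  # no matches -> identity
  p3 <- partition_special(decs[1:7])
  expect_identical(length(p3$community), 7L)
})

test_that("a known endosymbiont spike is recovered within sampling error", {
  study <- simulate_study(n_libraries = 1, clones_per_library = 150,
                          include_special = TRUE, endosymbiont_frac = 0.05,
                          chloroplast_frac = 0, seed = 61)
  refs <- study$refs
  m <- train_kmer_model(refs)
  decs <- lapply(study$libraries[[1]]$clones, function(cl) {
    consensus_taxonomy(classify_bootstrap(cl$fwd_read, m, seed = 1),
                       classify_bootstrap(revcomp(cl$rev_read), m, seed = 2),
                       clone_id = cl$clone_id)
  })
  p <- partition_special(Filter(function(d) d$status == "accepted", decs))
  tot <- length(p$community) + length(p$endosymbiont) + length(p$chloroplast)
  frac <- length(p$endosymbiont) / tot
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
})
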