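# Pairwise distances under the one-gap-run convention, average-neighbor
# clustering against a brute-force oracle, representatives and OTU tables.

test_that("distances implement the one-gap-run and N conventions", {
  # identical rows
  a <- alignment_matrix(c("s1", "s2"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_identical(pairwise_distance(a)["s1", "s2"], 0)

  # 3 substitutions over 100 comparable columns
  x <- strrep("A", 100)
  y <- paste0(strrep("A", 97), "CCC")
  b <- alignment_matrix(c("s1", "s2"), c(x, y))
  expect_equal(pairwise_distance(b)["s1", "s2"], 0.03)

  # a 5-column internal gap run plus 95 matches: 1 difference / 96 compared
  z <- paste0(strrep("A", 40), "-----", strrep("A", 55))
  cc <- alignment_matrix(c("s1", "s2"), c(x, z))
  expect_equal(pairwise_distance(cc)["s1", "s2"], 1 / 96)
  # ... and 5 differences / 100 under the eachgap convention
  expect_equal(pairwise_distance(cc, each_gap = TRUE)["s1", "s2"], 5 / 100)

  # terminal gap runs are ignored
  t1 <- paste0("-----", strrep("A", 90), "-----")
  dd <- alignment_matrix(c("s1", "s2"), c(x, t1))
  expect_identical(pairwise_distance(dd)["s1", "s2"], 0)

  # N mismatches a base; N opposite a gap drops the column
  ee <- alignment_matrix(c("s1", "s2"),
                         c("AANA", "AAAA"))
  expect_equal(pairwise_distance(ee)["s1", "s2"], 1 / 4)
  ff <- alignment_matrix(c("s1", "s2"), c("AAN-AA", "AA--AA"))
  expect_identical(pairwise_distance(ff)["s1", "s2"], 0)

  # internal gaps of concatenated rows are missing data, not differences
  gg <- alignment_matrix(c("s1", "s2"), c(x, z),
                         origin = c("assembled", "concatenated"))
  expect_identical(pairwise_distance(gg)["s1", "s2"], 0)

  # no comparable columns -> distance 1 with a warning
  hh <- alignment_matrix(c("s1", "s2"), c("AAA---", "---TTT"))
  expect_warning(d <- pairwise_distance(hh), "no comparable")
  expect_identical(d["s1", "s2"], 1)
})

test_that("distance matrices are symmetric with zero diagonal in [0,1]", {
  refs <- fixture_refs()
  aln <- alignment_matrix(refs$taxon_id, refs$sequence)
  d <- pairwise_distance(aln)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("average-neighbor clustering matches the brute-force oracle", {
  set.seed(1234)
  for (rep in 1:60) {
    n <- sample(8:12, 1)
    dm <- random_dist_matrix(n)
    cutoff <- runif(1, 0.01, 0.07)
    got <- average_neighbor_cluster(dm, cutoff)
    want <- oracle_average_linkage(dm, cutoff)
    expect_identical(canon_partition(got$clusters), canon_partition(want))
  }
})

test_that("clustering degenerates correctly and is order invariant", {
  # all pairs above the cutoff: singletons
  dm <- random_dist_matrix(6)
  dm[dm > 0] <- 0.5
  p <- average_neighbor_cluster(dm, 0.03)
  expect_length(p$clusters, 6)
  # one sequence
  one <- matrix(0, 1, 1, dimnames = list("x", "x"))
  expect_identical(average_neighbor_cluster(one, 0.03)$clusters, list("x"))
  # shuffling the input order leaves the partition unchanged
  set.seed(99)
  for (rep in 1:10) {
    dm <- random_dist_matrix(10)
    p1 <- average_neighbor_cluster(dm, 0.04)
    perm <- sample(nrow(dm))
    p2 <- average_neighbor_cluster(dm[perm, perm], 0.04)
    expect_identical(canon_partition(p1$clusters), canon_partition(p2$clusters))
  }
})

test_that("raising the cutoff never increases the cluster count", {
  set.seed(7)
  dm <- random_dist_matrix(12)
  ks <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08),
               function(ct) length(average_neighbor_cluster(dm, ct)$clusters),
               integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("representatives minimise total within-cluster distance", {
  dm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dm["A", "B"] <- dm["B", "A"] <- 0.01
  dm["A", "C"] <- dm["C", "A"] <- 0.02
  dm["B", "C"] <- dm["C", "B"] <- 0.03
  expect_identical(pick_representative(c("C", "B", "A"), dm), "A")
  expect_identical(pick_representative("Z", dm), "Z")
  # perfect symmetry -> smallest id
  sym <- matrix(0.05, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(sym) <- 0
  expect_identical(pick_representative(c("c", "b", "a"), sym), "a")
})

test_that("OTU tables conserve counts and ignore input order", {
  part <- structure(list(cutoff = 0.03,
                         clusters = list(c("a1", "a2", "b1"), c("b2", "b3"),
                                         "a3")),
                    class = "otu_partition")
  lib_of <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  tab <- build_otu_table(part, lib_of)
  expect_identical(sum(tab$counts), 6L)
  expect_equal(as.integer(rowSums(tab$counts)),
               unname(lengths(tab$members)))
  expect_equal(unname(colSums(tab$counts)), c(3, 3))
  # shuffled cluster/member order gives the identical table
  part2 <- structure(list(cutoff = 0.03,
                          clusters = list("a3", c("b3", "b2"),
                                          c("b1", "a2", "a1"))),
                     class = "otu_partition")
  tab2 <- build_otu_table(part2, lib_of)
  expect_identical(tab$counts, tab2$counts)
  # disjoint libraries produce a block structure
  part3 <- structure(list(cutoff = 0.03,
                          clusters = list(c("a1", "a2"), c("b1", "b2"))),
                     class = "otu_partition")
  tab3 <- build_otu_table(part3, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_identical(sort(as.vector(tab3$counts)), c(0L, 0L, 2L, 2L))
  expect_error(build_otu_table(part, lib_of[-1]), "not mapped")
})

test_that("OTU relabeling follows the dominant classified lineage", {
  lin <- function(genus) data.frame(
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F", genus = genus, stringsAsFactors = FALSE)
  # dominant genus absorbs unclassified members
  out <- relabel_otu_taxonomy(rbind(lin("G"), lin("G"), lin("unclassified")))
  expect_identical(unname(out[["genus"]]), "G")
  # even split -> unclassified genus, shared family kept
  out <- relabel_otu_taxonomy(rbind(lin("G1"), lin("G2")))
  expect_identical(unname(out[["genus"]]), "unclassified")
  expect_identical(unname(out[["family"]]), "F")
  # all unclassified at genus: nearest reference names the OTU
  refs <- fixture_refs()
  all_un <- rbind(lin("unclassified"), lin("unclassified"))
  out <- relabel_otu_taxonomy(all_un, rep_seq = refs$sequence[7],
                              refs = refs)
  expect_identical(unname(out[["genus"]]), paste0(refs$genus[7], "-like"))
  expect_error(relabel_otu_taxonomy(lin("G")[0, ]), "empty")
})

test_that("the 3% partition recovers true genera on synthetic data", {
  skip_if_not_installed("mclust")
  div <- c(taxon = 0.004, genus = 0.02, family = 0.03,
           order = 0.06, class = 0.10, phylum = 0.15)
  refs <- build_reference_set(6, 3, rank_divergence = div, seed = 71)
  aln <- alignment_matrix(refs$taxon_id, refs$sequence)
  dm <- pairwise_distance(aln)
  p <- average_neighbor_cluster(dm, 0.03)
  otu_of <- setNames(rep(seq_along(p$clusters), lengths(p$clusters)),
                     unlist(p$clusters))
  ari <- mclust::adjustedRandIndex(otu_of[refs$taxon_id], refs$genus)
  expect_gte(ari, 0.9)
})
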