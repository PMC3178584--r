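---
title: "Methods: OTU analysis of paired-end Sanger 16S clone libraries"
author: "cloneotu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTU analysis of paired-end Sanger 16S clone libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneotu)
```

## The study design being modelled

Sanger-era 16S surveys clone a ~1450 bp amplicon (bracketed by the
universal primers 27F and 1492R) and sequence every clone from both ends.
Two features dominate the downstream analysis and drive most of the design
choices in this package:

* **Partial, two-sided coverage.** A single ~700 nt read does not span the
  amplicon, and for roughly half of the clones the forward and reverse
  reads do not overlap at all. Those clones can only be represented as a
  *concatenated* row — the two reads placed in a common reference
  coordinate system with a gap-filled unread interior.
* **PCR chimeras.** Template switching during PCR joins the 5' portion of
  one template to the 3' portion of another. With both ends sequenced
  independently, a chimera whose parents belong to different families
  betrays itself by strongly supported, *conflicting* taxonomy
  assignments of its two reads; this taxonomic-conflict rule is the
  chimera screen implemented here.

The pipeline (`run_pipeline()`) chains the stages below, recording each
filtering decision in a ledger whose conservation property — stage *k*+1
consumes exactly what stage *k* retained — is enforced by tests.

## Quality masking

Bases with Phred quality below `q_min = 15` are replaced by `N`
(`mask_low_quality()`). The workflow this package reimplements prints the
rule as masking bases with quality *at or above* 15; applied literally that
would erase every usable base, so we treat it as a typographical slip and
mask *below* threshold. A `literal` flag preserves the printed reading for
auditability. `N` is carried through the pipeline as a non-gap character
that matches nothing.

## Assembly and gapped concatenation

`merge_pair()` searches for the best suffix–prefix overlap between the
forward read and the reverse-complemented reverse read. The acceptance
criterion — at least 30 nt of overlap at 90% identity, disagreements
resolved toward the higher-quality base — is not stated by the original
workflow; these defaults are common assembler practice and are exposed as
configuration (`min_overlap`, `min_identity`). Pairs that fail the
criterion are aligned read-by-read and joined by
`concatenate_nonoverlapping()`, which requires the two aligned spans to be
disjoint and fills the interior with gaps; in the rare case where the
aligned spans overlap slightly even though assembly failed, the pipeline
gives the forward read priority over the clashing columns.

## Reference-guided alignment

`align_to_reference()` picks the nearest reference by shared 8-mers and
aligns the query globally against it (Needleman–Wunsch via Biostrings,
end-gap free in the reference), then projects the query onto the
reference's alignment columns, dropping query bases that fall in
insertions. This replaces the covariance-model (secondary-structure) HMM
aligner used by the original workflow: at desk scale, with synthetic
queries derived from the same reference set, a pairwise projection is
exact enough and keeps the package dependency-free. The alignment width is
taken from the reference set rather than hard-coded.

Columns whose gap fraction strictly exceeds `max_gap_frac = 0.80` are then
trimmed (`trim_gap_columns()`; `N` is not a gap), and rows left with fewer
than `min_nongap = 300` nucleotides are removed (`filter_short()`; a row
with exactly 300 survives). Trimming is per-column — a failing "block" is
simply a maximal run of failing columns, so per-column evaluation
reproduces any block rule at the same threshold — and we derive the
trimmed columns from the rule rather than fixing them a priori.

## Taxonomy with bootstrap confidence

`train_kmer_model()` builds a per-genus naive-Bayes model over 8-mer
presence with add-half smoothing, standing in for the external classifier
service the original workflow submitted sequences to.
`classify_bootstrap()` scores all of a query's words, then resamples
`floor(W/8)` words with replacement 100 times; the support of a rank is
the percentage of resamples whose winning genus lies in the same clade,
which makes supports non-decreasing toward the root by construction.

`consensus_taxonomy()` merges the 5', 3' and full-length/concatenated
classifications. Each is truncated to its deepest rank passing the
threshold ladder (>75 genus, >80 family, >95 order, =100 class; phylum
and domain inherit the class rule so the ladder stays monotone). "Strongly
supported disagreement" is operationalised as: both inputs pass the rank's
threshold with different labels. Any such disagreement at family rank or
above yields `chimera_conflict` (conservative: the full-length input
participates symmetrically, and a single strongly supported dissent at
family+ suffices); disagreement confined to genus within one family
resolves to the 2-of-3 majority when one exists and otherwise to
"unclassified". Decisions matching configured special lineages
(*Wolbachia*, *Spiroplasma*, chloroplast, at any rank, case-insensitive)
are diverted by `partition_special()` before community analysis, with
counts conserved.

## Distances and OTU clustering

`pairwise_distance()` implements the clone-library distance convention:
columns gapped in both rows are ignored, terminal gap runs are ignored, a
maximal internal gap run in one row counts as one difference (and one
compared column) regardless of length, and `N` matches nothing — a
difference against a base, an ignored column against a gap. Two further
choices deserve note:

* The unread interior of a concatenated row encodes *absence of data*,
  not deletion, so those columns are ignored pairwise
  (`concat_missing = TRUE`). Trimming, by contrast, still sees them as
  gaps — which is what allows the 80% rule to remove the non-overlap
  region wholesale, as the original workflow's fixed trim positions did.
* Whether the original distance computation penalised every gap column
  separately cannot be determined from its description; the one-gap-run
  convention is the cited tool's documented default and `each_gap = TRUE`
  provides the alternative.

`average_neighbor_cluster()` is exact average-linkage agglomeration
(Lance–Williams update, recomputed means): merge the pair of clusters with
the smallest mean inter-cluster distance while that mean does not exceed
the cutoff (0.03 by default, i.e. 97% similarity). Ties break toward the
pair containing the lexicographically smallest member id, making the
partition invariant to input order; the suite verifies equality with a
brute-force oracle on hundreds of random instances. Representatives
minimise total within-cluster distance (ties to the smallest id), OTUs are
labeled `"<representative's library> <index>"`, and OTU lineages are
relabeled from the strict majority of members' classified labels at each
rank — an OTU whose members are all unclassified at genus is named after
the representative's nearest reference with an `-like` suffix, standing in
for the manual phylogeny-based naming of the original analysis.

## Diversity statistics

Chao1 uses the bias-corrected form `S_obs + n1(n1-1)/(2(n2+1))`, defined
even when no doubleton exists (real sparse libraries regularly have
`n2 = 0`). Shannon diversity uses natural logarithms (the cited tool's
default; a `base` argument gives log2), with evenness `H / ln S_obs`; a
single-OTU library has `H = 0` and its evenness (0/0) is reported as 1
with an explicit `evenness_defined = FALSE` flag. Rarefaction is the
analytic hypergeometric expectation computed with log-gamma, with the
classic variance including covariance terms; the default depth grid is 20
evenly spaced depths per library. Beta diversity reports both a
membership-based statistic (Jaccard on OTU incidence) and an
abundance-weighted one (fraction of pooled sequences in shared OTUs),
because the original survey's pairwise table does not say which it
contains.

## Trees, UniFrac and ordination

The tree over OTU representatives is neighbor joining (`ape::nj`) rather
than approximately-maximum-likelihood inference: NJ is deterministic,
dependency-free, and the UniFrac contract only needs a reasonable additive
tree. Negative NJ branch lengths are clamped to zero with the deficit
moved onto an adjacent branch (preserving leaf-to-leaf path lengths), and
the tree is rooted at the midpoint of a distant outgroup's branch — the
pipeline simulates a *Thermus*-like outgroup for the purpose, echoing the
original rooting on *Thermus thermophilus*.

`unweighted_unifrac()` is the presence/absence metric — the fraction of
branch length, in the subtree induced by two libraries' leaves, leading
exclusively to one library — chosen as primary because it matches the
cited tool's era and default; the membership matrix keeps counts so a
weighted variant can be layered on. Group significance
(`unifrac_permutation_test()`) pools libraries into bins (host diet by
default, since library-by-library comparisons do not survive
multiple-testing correction at these sample sizes), permutes the leaves'
membership rows, and uses the permutation-inclusive estimator
`p = (1 + #{perm >= obs}) / (1 + n_perm)` — which cannot return the
artifact p = 0 — with Bonferroni correction across the group pairs
tested. The permutation count defaults to 1000 (the original count is
unstated) and is configurable. `pcoa()` is classical metric scaling via
double-centred eigendecomposition; negative eigenvalues are reported, not
dropped, and percent variance is taken relative to the positive spectrum.

## The synthetic-data generator

`build_reference_set()` grows a balanced six-rank taxonomy from one random
amplicon by per-rank point substitution, with the divergence ladder
0.005 / 0.01 / 0.03 / 0.06 / 0.10 / 0.15 applied at taxon, genus, family,
order, class and phylum births respectively. This makes within-genus
identity exceed 97% (so the 3% cutoff roughly recovers genera) and orders
mean distances within-genus < within-family < between-family, which the
suite checks by exhaustive pairwise comparison. Primer sites are never
mutated. `simulate_study()` gives every library one dominant family at
weight 0.6 — the empirical pattern in which a handful of families
(Enterobacteriaceae-, Acetobacteraceae- or Lactobacillales-like lineages)
dominate any one host sample — and can spike *Wolbachia* and chloroplast
lineages to exercise the partitioning stage.

`sample_clone_library()` draws clone templates i.i.d. from the profile,
makes a configurable fraction bimeric (breakpoint uniform on the middle
80% of the amplicon, so both end-reads keep parental signal), and flips a
coin per clone for the non-overlap regime (default 0.5, the published
fraction). Read lengths target 700 nt — a typical Sanger figure; the
original read-length distribution is unstated — and are adjusted per
clone so the drawn overlap regime is geometrically consistent. Sequencing
error is substitution-only at rate 0.002, independent of the drawn
qualities; 0.5% of bases receive qualities below 15 and are later masked,
the realistic residue of vector- and quality-trimmed Sanger reads. The
chimera rate defaults to 2%, the order of magnitude implied by published
clone-library screens.

What the generator deliberately does not emulate: chromatogram-level
error structure, indels (an `indel_rate` knob exists but defaults to 0 so
alignment tests stay interpretable), PCR primer bias, 16S copy-number
variation, and
within-taxon polymorphism. Passing tests therefore demonstrate that the
*pipeline logic* is correct under the stated statistical structure, not
that any particular biological dataset would be reproduced bit-for-bit —
real data processed with different aligners and classifiers will differ
in detail.

## Numerical and degenerate-input choices

* All randomness flows from a single integer seed; stage seeds are
  derived arithmetically and stay inside the 32-bit range. Two runs with
  equal configuration are byte-identical.
* A sequence pair with no comparable columns gets distance 1.0 with a
  warning rather than an error, so one pathological row cannot abort a
  study.
* Clustering tie-breaks, representative tie-breaks and OTU ordering are
  all lexicographic on ids, making every table independent of input
  order.
* Libraries whose retained count falls below `min_library_size = 26`
  (the smallest library the original survey kept) are dropped whole, with
  a ledger entry, because diversity estimates on smaller samples are
  unreliable.
* The end-to-end validation runs 3 libraries x 100 clones and the
  permutation-calibration check uses 500 null replicates at 99
  permutations on 16-leaf trees; these sizes give stable statistics
  (binomial standard errors of a few percent) while keeping a full suite
  run on one CPU in minutes.

## Known limitations

The reference-guided aligner assumes queries are homologous to some
reference over their whole length; heavily chimeric queries between very
distant parents can align patchily (they are excluded by the taxonomy
conflict rule anyway). The naive-Bayes classifier shares the usual
limitation that supports are resampling confidences, not probabilities of
correctness. UniFrac p-values are conditional on the estimated tree — tree
uncertainty is not propagated. And the 3% cutoff recovers *genera* only
because the generator is calibrated that way; on real data the cutoff's
taxonomic meaning varies by lineage.
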