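Package: cloneotu
Title: OTU Analysis of Paired-End Sanger 16S rRNA Clone Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested reimplementation of the classic
    Sanger-era 16S rRNA clone-library workflow used to survey host-associated
    bacterial communities. Covers quality masking and assembly or gapped
    concatenation of paired end-reads, reference-guided alignment with
    high-gap column trimming and length filtering, k-mer naive-Bayes taxonomy
    with bootstrap confidence and consensus across 5'/3'/full-length
    classifications (including conflict-based chimera exclusion and
    endosymbiont/chloroplast partitioning), average-neighbor OTU clustering
    at a 3% cutoff with representative picking and taxonomy relabeling,
    alpha and beta diversity (Chao1, Shannon, Good's coverage, analytic
    rarefaction, shared-OTU similarity), and tree-based community comparison
    (neighbor joining, unweighted UniFrac with permutation tests, principal
    coordinates). A synthetic clone-library simulator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    picante,
    mclust,
    jsonlite
Config/testthat/edition: 3
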