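Package: phylomorph
Title: Congruence Between Colony Morphology and Molecular Phylogeny in
    Branching Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of whole-colony 3D morphology with
    molecular phylogeny for branching corals. Extracts branch-level
    morphometrics (thickness, spacing, branching rate and angles) from
    binary voxel volumes via anisotropy-aware distance transforms and
    3D curve skeletonization; builds average-linkage (UPGMA) morphological
    dendrograms; computes p-distances between aligned alleles with
    diploid homozygote-duplication averaging; derives unit-branch-length
    (topological) cophenetic distances from phylogenetic trees; and tests
    congruence between distance matrices with Mantel and CADM (Kendall's
    W) permutation tests. Includes generators for synthetic branching
    colonies with known ground-truth morphometrics and for diploid
    intron-like allele data with heterozygotes and hybrids, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    stats,
    utils,
    tiff,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
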