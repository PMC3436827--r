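Package: grbcontext
Title: Genomic Context Analysis of Ultraconserved Non-Coding Elements in
    Duplicated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the fate of ultraconserved non-coding
    elements (UCNEs) and the genomic regulatory blocks (GRBs) they form
    after whole-genome duplication. Detects UCNEs from pairwise genome
    alignments by sliding-window identity, finds their homologs in
    duplicated genomes by optimal local alignment with shuffle-calibrated
    E-values, classifies per-gene and per-cluster retention patterns
    (winner-takes-all, concordant, reciprocal), computes bitscore-weighted
    winner scores with a permutation null, reconstructs orthologous
    syntenic subclusters with assembly-aware merging, and simulates the
    post-duplication evolution of cooperative cis-regulatory element
    clusters. Includes a synthetic-genome generator with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
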