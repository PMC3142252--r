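Package: xprio
Title: Candidate Gene Prioritization by Annotation Filtering and Upstream
    Motif Discriminant Analysis
Version: 0.1.0
Author: xprio developers
Maintainer: xprio developers <xprio@example.org>
Description: Two-pronged prioritization of disease candidate genes on a
    chromosome. An annotation-based route scores genes against curated
    annotation-term gene lists in a binary evaluation grid and summarizes
    enrichment of known disease genes in the ranking. A sequence-based route
    selects representative transcription start sites from tag clusters,
    compiles class-labeled upstream regions ("contigs" pooled into
    "subgenomes"), screens canonical k-mers for overrepresentation with a
    fragment-shuffling permutation test, and classifies genes by linear
    discriminant analysis of oligomer counts with leave-one-out
    cross-validation and a posterior decision threshold. A synthetic-data
    module generates chromosomes, gene models, TSS tag clusters, planted
    motifs and term lists with known ground truth so the whole pipeline is
    testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    methods,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
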