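Package: synterna
Title: Positional Conservation Analysis of Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and categorizes long non-coding RNA (lncRNA) candidates
    (LincRNA, gene-associated transcriptional units, natural antisense
    transcripts), clusters them across species by reciprocal-best-hit Markov
    clustering at configurable identity cutoffs, labels lineage specificity,
    and tests whether lineage-specific lncRNAs are conserved by genomic
    position through synteny-anchor projection.  Includes a multi-lineage
    synthetic genome simulator with planted lncRNA conservation classes, a
    seeded local aligner with an exact Smith-Waterman reference, collinear
    anchor chaining, single-sequence RNA secondary-structure prediction with
    a reduced nearest-neighbour energy model, and a telomere-proximity
    statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
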