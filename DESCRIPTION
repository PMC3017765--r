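Package: famarch
Title: Gene Family Architecture: Intron Evolution, Phylogeny, Synteny and
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative genomic analysis of multigene families, modelled on
    insect carboxyl/cholinesterase (CCE) studies. Reads a genome (FASTA) and
    gene models (GFF3), extracts introns with GT/AG splice-site validation and
    codon-phase classification, projects intron positions onto a protein
    multiple sequence alignment to detect conserved intron positions and
    phases, estimates JTT maximum-likelihood protein distances and
    neighbor-joining/minimum-evolution trees with bootstrap support, detects
    tandem chromosomal gene clusters, infers cross-species microsynteny events
    (duplication, loss, split, fusion), and tabulates EST clone counts per
    gene and tissue. Includes a simulator that evolves gene families along a
    known tree with intron loss and gain, emitting FASTA/GFF3/TSV inputs plus
    truth files so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
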