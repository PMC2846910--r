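Package: trdrep
Title: Annotation and Repertoire Analysis of T Cell Receptor Delta Genes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Germline annotation and expressed-repertoire analysis of the
    T cell receptor delta (TRD) locus of gamma-delta T cell high species
    such as cattle. Parses gene-model tables and collapses redundant
    models, detects and scores recombination signal sequences
    (heptamer-spacer-nonamer, 12/23 rule), maps V domains onto the IMGT
    unique numbering with framework/CDR delineation and
    functional/ORF/pseudogene calls, classifies TRDV1 genes into
    phylogenetic sets with neighbor-joining trees built from p-distances,
    assigns rearranged cDNAs to germline V genes, extracts CDR3
    junctions, calls ordered multi-TRDD usage with P/N-region annotation,
    and summarizes diversity-gene usage. A synthetic locus and repertoire
    simulator with full recombination ground truth makes every pipeline
    stage testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
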