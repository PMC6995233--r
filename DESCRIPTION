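Package: retrocensus
Title: Census of Processed Pseudogenes and Transcript-End Mapping from Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs a conserved multi-exon gene across genomes, maps its
    transcript 5' and 3' ends from RNA-seq read evidence using tiled 60-bp
    probes and poly-A junction reads, detects and classifies its processed
    pseudogenes (retrocopies), and tests whether pseudogenes arose
    independently per species via neighbor-joining bootstrap phylogenies and
    per-species monophyly. Includes a synthetic locus and read simulator with
    a planted-truth ledger, a seed-and-extend local DNA aligner with
    BLAST-style affine-gap scoring presets, a Needleman-Wunsch global aligner,
    open-reading-frame finding with conceptual translation, and
    single-nucleotide discriminating expression probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
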