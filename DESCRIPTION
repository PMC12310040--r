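Package: motifscape
Title: Canonical Motif Curation and Positional Analysis of Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the post-peak-calling analysis of transcription
    factor (TF) ChIP-seq data: a position weight matrix (PWM) data model
    with MEME-minimal and JASPAR I/O, Pearson-correlation motif
    similarity, FIMO-style PWM scanning with exact p-values from a
    dynamic-programming null distribution, a decision procedure that
    separates canonical from co-occurring motifs, consensus core motifs
    for TF families, classification of ChIP-seq peaks into canonical,
    tethered and co-binding modes with protein-interaction shortest-path
    typing of co-binding partners, and positional analysis of conserved
    binding sites relative to transcription start sites, gene structure,
    cis-regulatory elements and CTCF-bound sites. A synthetic-data
    generator with a planted ground truth makes every stage testable
    end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    igraph,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
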