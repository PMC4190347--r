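Package: peakshare
Title: Multi-Tissue ChIP-Seq Peak Comparison, Motif Modules and ChIP-qPCR Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcription-factor ChIP-seq peak sets
    across tissues: MACS-style peak table import, nearest-TSS gene
    association with distance and expression filters, exclusive
    tissue-sharing classification of peaks by fractional interval overlap,
    genomic-location classification of peak summits, E-box consensus and
    position-weight-matrix motif scanning with co-occurrence ("module")
    detection within a fixed spacing window, shuffle-based motif enrichment
    z-scores, and delta-delta-Ct fold-enrichment statistics for ChIP-qPCR
    validation. Includes a seeded synthetic-data generator (toy genome,
    annotation, designed overlap structure, planted motifs, qPCR panels)
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
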