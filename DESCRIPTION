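Package: somiteMap
Title: Integrated RNA-seq and ATAC-seq Analysis of Somite Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for matched bulk RNA-seq and ATAC-seq
    profiles of maturing mouse somites. Implements quality-control gating of
    ATAC libraries (insert-size distribution scoring, TSS enrichment,
    fraction of reads in peaks), trend-aware loess offset normalization of
    windowed fragment counts, removal of unwanted variation via principal
    components of design residuals with permutation-based dimension
    selection, negative-binomial differential testing under stage-by-somite
    contrast families, window-level differential accessibility with region
    merging and Simes p-value combination, genomic-context classification of
    peaks, transcription-factor motif accessibility deviations against
    GC/accessibility-matched backgrounds, and peak-gene regulatory linkage
    with signed TF-gene regulation scores. A synthetic-data generator with a
    planted truth set supports calibration and recovery testing of every
    stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    edgeR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
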