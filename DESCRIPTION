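Package: epidecodr
Title: Barcode-ChIP Quantification of the Local Proteome at a Single Locus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for pooled barcode-ChIP ("Epi-Decoder") experiments, in
    which the occupancy of each epitope-tagged protein at a common barcoded
    locus is read out by counting strain-specific DNA barcodes in
    immunoprecipitated (IP) versus input chromatin. Provides a synthetic-data
    generator (barcode libraries with guaranteed Hamming separation,
    ground-truth binding kinetics, FASTQ read simulation with substitution
    errors), index demultiplexing, anchored barcode extraction,
    error-tolerant barcode matching and counting, IP/input binding scores
    with triple-barcode replicate aggregation and Spearman QC, time-course
    and condition contrasts with eviction/recruitment classification, and
    spike-in-normalized qPCR helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
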