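Package: accessons
Title: Accesson-Based Analysis of Single-Cell Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Groups genome-wide scATAC-seq peaks that fluctuate together
    across single cells into "accessons", densifies the sparse cell-by-peak
    fragment count matrix into a cell-by-accesson matrix, and drives cell
    clustering (Louvain or connectivity-constrained Ward), Adjusted Rand
    Index evaluation, TSS-window gene activity scoring, differential
    analysis, Fisher's-exact association of cluster sets, accesson-based
    super-enhancer calling, and low-dimensional trajectory features from it.
    Includes a synthetic data generator with planted cell types, peak
    blocks, and super-enhancer loci for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
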