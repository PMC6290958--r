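Package: npm1mrd
Title: Ultradeep Amplicon Sequencing MRD Assay for NPM1-Mutated AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end measurable residual disease (MRD) pipeline for
    NPM1-mutated acute myeloid leukemia based on ultradeep dual-indexed
    amplicon sequencing of NPM1 exon 12. Implements seeded read simulation
    with known truth, dual-index demultiplexing with index-hopping
    quarantine, paired-end read self-assembly, targeted banded-alignment
    insertion calling with a two-supporting-read threshold and variant
    allele frequency (VAF) estimation, assay validation statistics (limit
    of blank, limit of detection, Levey-Jennings precision-control
    monitoring), and patient-level MRD classification by PI/PC log
    reduction with ROC/Youden cutoff selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
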