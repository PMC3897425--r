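Package: pscc
Title: Population-Scale Copy Number Variant Calling from Low-Coverage
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Read-depth copy number variant (CNV) detection designed for
    low-coverage (around 2x) and ultra-low-coverage (around 0.2x)
    whole-genome sequencing. Per-window read counts are corrected in two
    steps: a within-sample median rescaling by local GC content, followed
    by normalization against the per-window mean of a panel of control
    samples, yielding a relative copy ratio track. Segments are located by
    a binary segmentation driven by the two-sample Wald-Wolfowitz runs
    test, and each segment is genotyped with a combined scheme: a
    rank-based self-test against the rest of the genome and a
    parallelism-test against the variability implied by the control
    panel's per-window standard deviations. Includes equal-expected-count
    observation window construction from reference mappability, per-window
    read counting from BAM files, a window-level simulator with GC and
    shared multiplicative biases, and call-level sensitivity/specificity
    evaluation for power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
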