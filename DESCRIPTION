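Package: nanodiff
Title: Comparative Detection of RNA Modifications from Nanopore Current Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Training-free, comparative detection of RNA modifications from
    nanopore direct RNA sequencing. Per-read current features (mean, median,
    standard deviation, dwell time) extracted from signal-to-reference
    alignments of a native sample are contrasted against an unmodified in
    vitro transcribed (IVT) control at every reference position using
    multivariate (MANOVA), logistic-regression or Kolmogorov-Smirnov tests
    with Benjamini-Hochberg correction. Significant sites are filtered with
    calibrated effect-size and coverage cutoffs, merged into contiguous
    regions and written as BED. Includes evaluation utilities (shift-window
    matching against known sites, precision/recall/F1, ROC-AUC, min-rule
    region intersection), a differential filter for modified-basecalling
    bedMethyl output, and a seeded simulator of paired native/IVT feature
    tables with planted modification footprints.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, pROC, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
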