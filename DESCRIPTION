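Package: cpiem
Title: Detecting Cooperatively Bound Transcription Factor Pairs from
    ChIP-Seq Peak Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects genomic regions where a pair of transcription factors
    binds DNA cooperatively, using only the peak intensities of their
    overlapping ChIP-seq peaks. Fits a nine-parameter two-component
    product-marginal mixture (log-normal, gamma or Gaussian marginals) to
    target/partner intensity pairs by expectation maximization and converts
    the fit into a per-region Bayes posterior probability of cooperative
    binding. Also provides knockout-based ground-truth labeling from
    ChIP-seq of the target factor after partner deletion (peak loss and
    rank-change evidence), a peak summit-distance baseline detector, a
    cooperative-index utility for external occupancy-model predictions,
    a PWM best-hit indirect-binding filter with a negative-control
    percentile threshold, ROC/precision-recall evaluation machinery, and a
    fully labeled synthetic-data generator so the whole pipeline can be
    exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
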