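Package: popcoding
Title: Static and Dynamic Population Coding Analysis for Prefrontal Single Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings from associative
    learning tasks: behavioral learning-point estimation from binomial
    moving-average performance curves, waveform-based classification of
    broad- and narrow-spiking cells (trough-to-peak durations, Hartigan dip
    test, Gaussian mixture cutoffs), omega-squared explained-variance
    selectivity time courses, cross-temporal population decoding with a
    maximum-correlation classifier, static/dynamic classification of
    decoding generalization with a stability index, and cluster-based
    permutation statistics.  Includes a synthetic-session generator with
    known ground truth so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
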