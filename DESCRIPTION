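Package: meltbarcode
Title: Species Assignment from Closed-Tube Barcoding Melt-Curve Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for species identification from two-channel real-time PCR
    melt-curve fluorescent signatures, as used in closed-tube DNA barcoding of
    sharks and rays. Provides a seedable generative model of two-segment melt
    curves for a 28-species elasmobranch panel, Savitzky-Golay derivative
    signature extraction with internal temperature-marker correction,
    quality-control filtering of hybridization failures and inconsistent
    replicates, merged two-segment feature assembly, a feedforward neural
    network classifier trained by stochastic gradient descent with l1/l2
    regularization and random grid search, and confusion-matrix and
    species-distinguishability reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
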