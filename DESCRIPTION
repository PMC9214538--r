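Package: fifspec
Title: Fluorescence Intensity Fluctuation Spectrometry and SpIDA Brightness
    Analysis for Confocal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies the oligomeric state of fluorophore-tagged membrane
    proteins from laser-scanning confocal images.  Implements spatial
    intensity distribution analysis (SpIDA) quantal-brightness calibration
    with monomeric-equivalent-unit classification, fluorescence intensity
    fluctuation (FIF) spectrometry (region-of-interest segmentation,
    per-segment effective-brightness and protomer-concentration estimation,
    brightness spectrograms, and constrained multi-Gaussian decomposition
    into monomer/dimer/oligomer mole fractions), numerical evaluation of the
    confocal point-spread-function shape factor gamma, and a forward
    simulator of confocal images of membranes carrying known oligomer
    mixtures with closed-form moment oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
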