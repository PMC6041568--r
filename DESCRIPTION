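Package: paddyspec
Title: Near-Surface Imaging Spectroscopy of Paddy Rice for Leaf Nitrogen Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating rice leaf nitrogen
    concentration (LNC, percent of leaf dry mass) from millimetre-scale
    hyperspectral imagery. Provides a synthetic scene generator for paddy-rice
    canopies with known ground truth; ENVI-style cube input/output with
    radiometric calibration, spectral subsetting and minimum-noise-fraction
    denoising; a dyadic spatial-resolution ladder with block aggregation; a
    sunlit/shaded leaf and panicle pixel classifier driven by EVI, PRI and
    TCARI thresholds with green-fraction-matched threshold adaptation; a
    registry of 16 published nitrogen-related vegetation indices and
    convex-hull continuum removal; stage-specific LNC~VI models, partial
    least squares regression and Gaussian process regression with per-band
    relevance; and a resolution-sensitivity sweep with an optimal-resolution
    selection rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    optparse
Config/testthat/edition: 3
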