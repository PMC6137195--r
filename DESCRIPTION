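Package: tresoil
Title: Time-Resolved Emission Fluorescence Chemometrics for Edible-Oil
    Adulteration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying adulteration of camellia oil with cheaper
    vegetable oils from time-resolved emission fluorescence (TRES) measured by
    time-correlated single photon counting. Provides a synthetic TRES generator
    (trilinear fluorophore mixtures, instrument response convolution, Poisson
    counting noise), spectral pretreatment (standard normal variate and
    Savitzky-Golay smoothing along the emission mode), multi-exponential
    reconvolution lifetime fitting with Poisson weighting and component-number
    selection, PARAFAC trilinear decomposition by alternating least squares with
    the core consistency diagnostic and split-half validation, feed-forward
    neural-network calibration of adulteration level from PARAFAC sample scores
    with leave-one-out cross-validation, and a detection limit determined by
    Duncan's multiple range test on replicate intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    minpack.lm,
    nnet,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
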