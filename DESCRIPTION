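Package: hsifuse
Title: Fusion of Complementary Hyperspectral Imaging Systems for Fruit
    Bruise Detection
Version: 0.1.0
Authors@R:
    person("hsifuse", "developers", email = "hsifuse@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting internal bruises in fruit from mean
    reflectance spectra acquired by two hyperspectral imaging systems with
    complementary spectral ranges (a visible/near-infrared push-broom
    imager and a short-wave infrared liquid crystal tunable filter
    imager). Provides reflectance calibration and mask-based mean-spectrum
    extraction from ENVI cubes, probability-calibrated partial least
    squares discriminant analysis (PLS-DA) with a Gaussian class-density
    cut-off, random-frog wavelength selection, fusion of the two
    instruments at the data, feature, and decision level (weighted
    majority vote, Bayesian combination, and fuzzy-template rules),
    evaluation utilities (ROC/AUC, agreement partition), and a seeded
    synthetic-data generator emulating the two instruments for testing
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
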