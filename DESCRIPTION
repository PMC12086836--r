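Package: kubonet
Title: Neural-Network Classification of Simulated Two-Dimensional Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates linear and third-order two-dimensional infrared (2D IR)
    signals under the Kubo line-shape model with anharmonicity and vibrational
    lifetime decay, generates labeled binary-classification datasets centered
    on a percent-different-magnitude (PDM) boundary in Kubo parameter space
    with boundary-focused half-Cauchy sampling and SNR-controlled Gaussian
    noise, and trains compact residual convolutional classifiers with
    Brier-score early stopping. Includes evaluation utilities mapping
    classification skill (Brier Skill Score) across single
    (pump-time, waiting-time) spectral slices, spectrum normalization and
    augmentation routines for experimental-style frequency-frequency spectra,
    and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
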