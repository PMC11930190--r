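Package: dryspec
Title: FTIR Chemometrics for Drying-Temperature Discrimination and
    Taste-Compound Calibration
Version: 0.1.0
Authors@R:
    person("dryspec", "maintainers", email = "dryspec@example.org",
           role = c("aut", "cre"))
Description: An end-to-end chemometrics toolkit for attenuated total
    reflectance Fourier-transform infrared (ATR-FTIR) spectra of dried
    mushroom powders. Provides a synthetic spectrum and taste-compound
    generator with class-dependent band intensities, scatter and baseline
    artefacts; spectral pretreatments (multiplicative scatter correction,
    standard normal variate, Savitzky-Golay smoothing and derivatives, and
    their combinations); deterministic Kennard-Stone sample partitioning;
    generalized two-dimensional correlation spectroscopy (synchronous maps);
    PLS-DA classification with VIP scores, cross-validation and permutation
    testing; per-compound PLSR calibration with RMSEP and RPD; a small
    seeded residual convolutional network for classifying synchronous 2D
    correlation images; differential-metabolite screening (VIP > 1,
    P < 0.05) with concentration PCA and cluster-heatmap ordering; and a
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
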