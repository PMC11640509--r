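Package: nirpear
Title: Near-Infrared Maturity Assessment of 'Starkrimson' Pears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometrics pipeline for assessing harvest maturity of
    'Starkrimson' pears from Fourier-transform near-infrared (NIR)
    absorbance spectra. Implements spectral pretreatments (Savitzky-Golay
    smoothing and derivatives, standard normal variate, multiplicative
    scatter correction), competitive adaptive reweighted sampling (CARS)
    wavelength selection, Kennard-Stone sample partitioning, NIPALS partial
    least squares regression of four maturity indices (Streif, RPI, IQI and
    the radar-polygon-area visual ripeness index VRPI), and three-class
    maturity classification (unripe / ripe / over-ripe) with five
    classifiers evaluated by confusion matrix and classification accuracy.
    A seeded synthetic-orchard generator emulates the spectra, per-fruit
    quality tables and post-ripening batch tables of a four-harvest study
    design, so that every pipeline stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
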