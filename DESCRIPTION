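Package: serscal
Title: Quantification of Food Antiseptics from SERS Spectra by Partial
    Least Squares Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multivariate calibration of surface-enhanced Raman scattering
    (SERS) spectra for quantifying the food antiseptics potassium sorbate
    (PS) and sodium benzoate (SB), alone and in mixtures with overlapping
    characteristic bands. Provides a from-scratch univariate-response
    partial least squares regression (NIPALS PLS1) fitter with
    leave-one-out selection of the number of latent variables, spectral
    window (region-of-interest) restriction, a synthetic SERS spectrum
    generator with concentration-proportional Lorentzian bands,
    site-to-site enhancement variability and additive noise, and
    end-to-end calibration/validation experiments reporting R-squared and
    RMSE for single-analyte and mixture designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
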