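Package: boletespec
Title: Chemometrics and Two-Dimensional Correlation Spectroscopy for Bolete Species Authentication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for vibrational-spectroscopy chemometrics of wild edible
    boletes. Generates synthetic FT-NIR and ATR-FTIR absorbance spectra linked
    to amino-acid marker concentrations for five bolete species; computes
    synchronous and asynchronous two-dimensional correlation spectra (Noda
    generalised 2D correlation) with auto/cross-peak detection and the
    sequential-order sign rule; partitions sample sets with the Kennard-Stone
    and Kennard-Stone duplex algorithms; fits NIPALS partial least squares
    models for species discrimination (PLS-DA) and marker-concentration
    regression (PLSR) with cross-validation, VIP variable screening, RPD
    validation metrics and label-permutation testing; screens markers with
    one-way ANOVA plus Duncan's multiple range test; and trains a compact
    12-layer residual convolutional network on rendered correlation images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
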