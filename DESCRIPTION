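Package: specdx
Title: Chemometric Discrimination of Biofluid ATR-FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class discrimination of attenuated total
    reflection Fourier-transform infrared (ATR-FTIR) biofluid spectra.
    Implements the full chemometric pipeline used in clinical spectral
    fingerprinting studies: biofingerprint-region cutting, Savitzky-Golay
    smoothing, automatic weighted least-squares (AWLS) baseline correction,
    Amide-I normalisation, Kennard-Stone train/validation/test splitting,
    principal component analysis, wavenumber selection by the successive
    projections algorithm (SPA) and a genetic algorithm (GA) scored by a
    validation-set Mahalanobis cost function, linear and quadratic
    discriminant analysis and RBF support vector machines, and
    confusion-matrix figures of merit. Includes a synthetic cohort
    generator that emulates a case/control plasma study design so the
    whole pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
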