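Package: taglobal
Title: Global and Lifetime-Distribution Analysis of Ultrafast Transient
    Absorption and Fluorescence Decays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for femtosecond-to-nanosecond pump-probe
    spectroscopy of photoactive proteins. Provides maximum-entropy lifetime
    distribution analysis (LDA) of differential-absorbance matrices on a
    log-spaced lifetime grid with l-curve regularization selection, the
    dynamical-content statistic and decay-associated difference spectra
    (DADS); global kinetic analysis (GKA) by variable projection with a
    fitted Gaussian instrument response function, SVD-based component-count
    selection, sequential-model concentration profiles and
    evolution-associated difference spectra (EADS); reconvolution fitting of
    fluorescence decays (upconversion and TCSPC style); chirp correction,
    solvent subtraction, logarithmic time averaging and baseline noise
    estimation; and a synthetic-data generator emulating broadband
    supercontinuum probe measurements so the whole chain is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
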