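Package: cannaqnmr
Title: Quantitative 1H NMR Screening of Cannabinoids in CBD Oils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening cannabinoids (CBD, Delta9-THC, Delta8-THC,
    CBN) in CBD oils by quantitative 1H NMR. Implements time-domain spectral
    processing (exponential apodization, zero filling, Fourier transform,
    automatic phase and baseline correction, TMS referencing), external-standard
    quantification by the PULCON/ERETIC principle with empirical saturation
    correction factors, overlap-robust doublet line fitting on the broad CBD
    aromatic hump, and a full method-validation battery (calibration linearity,
    DIN 32645 detection and quantification limits, recovery, precision with a
    Shapiro-Wilk normality gate, stability, and regression-based comparison
    against a reference method). A synthetic-spectrum generator emulates
    CBD-oil matrices so the entire pipeline is testable without a spectrometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
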