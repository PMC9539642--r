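Package: nirscal
Title: Multi-Trait NIRS Calibration with Modified Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Near-infrared reflectance spectroscopy (NIRS) calibration
    pipeline for nutritional phenotyping of seed germplasm. Implements
    spectral pretreatment (standard normal variate, detrending and
    WinISI-style gap-segment derivative "math treatments"), modified
    partial least squares (MPLS) regression with cross-validated factor
    selection and residual-outlier elimination, external validation
    statistics (RSQ, bias, slope, SEP, RPD), calibration-set design by
    Ward clustering and rank-order splitting, paired t-tests and
    strictly-parallel reliability checks for model applicability, and a
    synthetic spectra generator so the whole pipeline can be exercised
    at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
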