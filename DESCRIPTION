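Package: psrcvd
Title: Phase-Space Reconstruction Screening of Localized ECG Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects cardiovascular abnormality from single-lead ECG by
    delay-embedding the localized diagnostic features (PR interval, QRS
    complex, QT interval) into two-dimensional phase portraits, box-counting
    the occupied pixels, and tracking the sliding-window coefficient of
    variation of the box counts against a learned two-threshold three-class
    decision rule. Includes Haar-wavelet beat delineation, a synthetic ECG
    generator with fiducial ground truth for validation, and the
    accompanying diagnostic-accuracy and hypothesis-testing statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
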