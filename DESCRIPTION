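Package: nrcid
Title: Compression-Based ECG Biometric Identification with Finite-Context Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biometric identification from single-lead ECG using
    compression-based similarity. Recordings are low-pass filtered,
    first-differenced and discretised by an equal-frequency quantizer;
    per-subject order-k finite-context models are trained on the resulting
    symbol sequences and test segments are attributed to the subject whose
    model yields the minimum Normalized Relative Compression (NRC).
    Includes a parametric synthetic ECG cohort generator (Gaussian PQRST
    wave model with subject, session, electrode-placement and movement
    factors) and drivers for four acquisition-protocol studies: movement,
    electrode-placement transfer, session gap, and test-segment duration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    data.table,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
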