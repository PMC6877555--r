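Package: gazedecode
Title: Decoding Stimulus Identity from Fixational Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to detect whether eye-tracking recordings made under
    attempted fixation carry stimulus-identity information, a confound for
    neural decoding studies. Implements the complete analysis chain: blink
    repair, zero-phase Butterworth low-pass filtering, downsampling, trial
    epoching and run-median centering; per-trial summary features; stratified
    cross-validated multiclass decoding with a linear maximum-margin
    classifier and label-permutation inference; median-based elliptic
    velocity-threshold microsaccade detection; distance- and velocity-based
    fixation-violation trial filtering with threshold sweeps; and group-level
    signed-rank tests and Spearman correlations. A seeded generator of
    synthetic binocular fixation sessions (drift, microsaccades, blinks, and
    an optional orientation-dependent gaze bias) makes the whole pipeline
    exercisable without access to recorded participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
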