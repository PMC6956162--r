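Package: dicmflex
Title: Dominant Intrinsic Coupling Modes and Flexibility of Dynamic
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity for multichannel
    band-limited recordings (e.g., resting-state MEG). Implements five
    windowed coupling estimators (amplitude envelope correlation, imaginary
    phase-locking value, phase-amplitude coupling, delay symbolic transfer
    entropy with neural-gas symbolisation, and the directed phase lag index),
    surrogate-based significance with false-discovery-rate control, selection
    of the dominant intrinsic coupling mode per sensor pair and time window,
    topological filtering by orthogonal minimal spanning trees, lobar
    aggregation into mean-subgraph-strength and fractional-occupancy
    features, a global flexibility index, age-curve model selection, and
    SVM/SVR age prediction. Includes a synthetic-data generator that plants
    each coupling mode with controllable strength so the whole pipeline is
    testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
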