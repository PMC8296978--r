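Package: envtrack
Title: Speech Envelope Tracking and Representational Similarity Analysis
    for EEG and Recurrent Network Activations
Version: 0.1.0
Authors@R:
    person("envtrack", "developers", email = "envtrack@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing human EEG dynamics with the hidden-layer
    dynamics of a speech-recognition recurrent network. Implements the
    stimulus-envelope preprocessing chain (Hilbert envelope, least-squares
    FIR low-pass, rectified first derivative, unit-area normalisation),
    lagged cross-correlation analysis of envelope tracking with matched and
    non-matching null pairings and peak statistics, representational
    similarity analysis (Euclidean representational dissimilarity matrices,
    Spearman comparison, noise ceilings, band-resolved and per-electrode
    maps), surrogate untrained-network ensembles as baselines, and a
    seeded synthetic-data generator that emulates the statistical structure
    of the assumed envelope-following response so the whole pipeline is
    testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
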