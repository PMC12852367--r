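Package: sleeposc
Title: Slow-Oscillation, Spindle Coupling and Spectral-Slope Analysis for
    Stimulated Nap Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nap-sleep EEG recorded around blocked
    slow-oscillatory transcranial current stimulation. Detects slow
    oscillations (SO) with individualized percentile amplitude thresholds,
    computes SO-locked Morlet time-frequency maps with threshold-free
    cluster enhancement (TFCE) permutation statistics, quantifies
    event-locked SO-spindle phase-amplitude coupling with circular
    statistics (Watson-Williams test, resultant vector length), estimates
    the aperiodic 1/f spectral slope as an excitation/inhibition proxy, and
    runs the group-level repeated-measures statistics including chronotype
    moderation. Includes a synthetic polysomnography generator with ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
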