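Package: errdecode
Title: Ensemble Decoding of the Identity of Sensory Prediction Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of population codes for mis-predicted
    sensory events. Generates odor-guided choice sessions with blockwise
    transitions in reward number and flavor, inhomogeneous-Poisson spike
    trains with planted value- and identity-error responses, waveform
    features, and multivoxel response-pattern datasets. Implements
    waveform-based dopamine unit classification with leave-one-out cluster
    assignment, event-warped spike-train concatenation and sliding-window
    binning, transition difference scores, correlation-template
    pseudoensemble decoding with label-shuffle permutation nulls
    (time-resolved, sliding trial sets, four-class early/late confusion
    analysis, decoding-latency scan), and nested cross-validated linear
    support-vector decoding of multivoxel patterns with confusion-matrix
    pattern permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
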