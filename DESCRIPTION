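Package: ratingsdt
Title: Unequal-Variance Signal Detection Modelling of Rating Data and
    Graded Physiological Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits unequal-variance Gaussian signal detection models to
    six-point confidence-rating data from near-threshold detection
    experiments, estimates decision criteria from rating-scale ROC
    curves, and predicts per-rating mean response amplitudes as
    truncated-Gaussian conditional means.  Includes two competitor
    models (a bimodal-signal bifurcation model and a discrete threshold
    model), behavioral summaries (d-prime, criterion, per-rating
    positive and negative predictive values, pupil-baseline quintile
    and chronological-split detection rates), a pupillometry
    preprocessing pipeline (blink interpolation, low-pass filtering,
    epoching, divisive baseline correction, pupil dilation response
    derivative), temporal cluster-based permutation tests and
    repeated-measures contrast statistics, and a synthetic-data
    generator that emulates the full experimental design so that every
    stage of the pipeline can be exercised end-to-end without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
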