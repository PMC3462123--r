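Package: sleepdhmm
Title: Transition-Constrained Discrete Hidden Markov Models for Automatic Sleep Staging
Version: 0.1.0
Authors@R:
    person("sleepdhmm", "developers", email = "sleepdhmm@example.org", role = c("aut", "cre"))
Description: An end-to-end automatic sleep-staging pipeline built around a
    transition-constrained discrete hidden Markov model (DHMM). Polysomnographic
    signals (one EEG, one EOG, one chin EMG channel) are resampled to 256 Hz,
    band-pass filtered with eighth-order Butterworth filters, segmented into
    30-second epochs and summarised by thirteen spectral and temporal features
    (band powers, power ratios, mean spectral frequency, alpha/spindle/slow-wave
    duration ratios and EMG energy). Feature vectors are vector-quantized with a
    k-means codebook initialised on per-dimension subintervals, and the resulting
    observation codes drive a five-state DHMM whose transition matrix is pinned
    to zero on physiologically impossible stage transitions. Includes a
    stage-labelled synthetic PSG generator, scaled forward and Viterbi
    algorithms, count-based supervised training and Viterbi re-estimation,
    Cohen's kappa and overall-agreement scoring, and a repeated two-fold
    cross-validation protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
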