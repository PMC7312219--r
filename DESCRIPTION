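Package: eegselect
Title: Multi-Objective EEG Channel Selection for Epileptic-Seizure Classification
Version: 0.1.0
Authors@R:
    person("EEG", "Select Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper-based selection of EEG channel subsets for
    epileptic-seizure classification, posed as a bi-objective optimization
    problem: maximize cross-validated classification accuracy while
    minimizing the number of electrodes. Per-channel signals are decomposed
    into oscillatory sub-bands by empirical mode decomposition (EMD) or a
    four-level biorthogonal-2.2 discrete wavelet transform, and each
    sub-band is summarized by two log-energy features (instantaneous and
    Teager) and two fractal dimensions (Higuchi and Petrosian). Candidate
    channel subsets are scored by a four-classifier portfolio (kernel
    margin classifier, k-nearest neighbours, random forest, Gaussian naive
    Bayes) under stratified cross-validation, and searched with
    from-scratch NSGA-II and NSGA-III implementations plus a greedy
    backward-elimination baseline. Includes a synthetic multichannel EEG
    generator with planted informative channels, EDF input/output, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
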