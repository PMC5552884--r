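Package: hbci
Title: Hybrid Brain-Computer Interfaces for Group Decision Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates per-trial decision confidence from EEG and response
    times and aggregates individual binary decisions into group decisions
    by confidence-weighted majority voting. Provides a synthetic-cohort
    simulator for a rapid visual-search experiment (continuous
    multichannel EEG with event markers plus behavioural tables), an EEG
    preprocessing chain (earlobe re-referencing, linear-phase FIR
    band-pass, ocular-artefact regression, stimulus- and response-locked
    epoching conditioned to a common 48-sample grid at 32 Hz), Common
    Spatial Pattern feature extraction trained on decision correctness,
    an L2-regularised logistic confidence model with cross-validated
    regularisation selection, weighted-majority aggregation with seeded
    tie-breaking over exhaustively enumerated groups, and an evaluation
    harness with outer 10-fold cross-validation, Wilcoxon signed-rank and
    Kruskal-Wallis contrasts, event-related-potential grand averages and
    moving-average error dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
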