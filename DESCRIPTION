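Package: ictalnet
Title: Personalized Ictal Pattern Detection for RNS Intracranial EEG
Version: 0.1.0
Authors@R:
    person("RNS", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects electrographic seizures (ictal patterns) in 90-second,
    4-channel intracranial EEG epochs recorded by a responsive
    neurostimulation (RNS) device, and regresses their onset time. The
    detector is a patient-conditioned 1-D residual convolutional network
    (23 convolutional layers, 11 residual blocks) trained with a joint
    cross-entropy plus Huber loss by plain SGD under a cyclical learning
    rate. The package also provides EDF-based epoch I/O, a synthetic
    RNS-style cohort simulator with known onsets and detector-confound
    classes, label-preserving training augmentations (pad-and-crop,
    amplitude rescaling), and a seed-based leave-one-patient-out
    evaluation framework reporting AUPRC, onset mean absolute error and
    a +/- 5 s onset tolerance fraction, with Kruskal-Wallis comparisons
    across implant sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
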