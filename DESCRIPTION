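Package: nmprobe
Title: Active Probing of Coupled Neural Mass Models for Seizure Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two bidirectionally coupled Wendling-type neural mass
    models of the hippocampal CA1 region with low-frequency periodic probing
    stimulation, integrating the stochastic delay differential system with the
    Euler-Maruyama scheme. Provides the full evaluation pipeline for
    stimulation-based seizure forecasting: post-stimulus epoch extraction,
    early-warning features (variance, skewness, kurtosis, lag-1
    autocorrelation, inter-population mutual information), moving-average
    smoothing, Spearman rank correlation of feature series against a linearly
    ramped ictogenic parameter (excitatory gain, slow inhibitory gain, or
    inter-population coupling), amplitude sweeps with Tukey HSD comparison
    against passive observation, spike and ictal-onset detection, and a
    pro-ictal safety experiment on onset latencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
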