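Package: mdephys
Title: Intrinsic Electrophysiology of Thalamocortical Neurons: Feature
    Extraction, Spike Classification, and Estimation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for episodic current-clamp recordings of
    thalamic relay neurons. Extracts subthreshold intrinsic properties
    (resting membrane potential, membrane time constant, input resistance,
    HCN-mediated voltage sag, afterhyperpolarization), detects and
    classifies action potentials into burst, tonic, and rebound firing
    modes using interspike-interval rules with third-derivative threshold
    estimation, and measures rheobase and accommodation. Group comparisons
    use nonparametric estimation statistics: Mann-Whitney and Wilcoxon
    tests, order-statistic median confidence intervals, bootstrap
    median-difference intervals, eta-squared effect sizes, and Spearman
    correlation. Includes a single-compartment conductance-based simulator
    (leak, HCN, T-type calcium, exponential spiking) that generates
    recordings with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
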