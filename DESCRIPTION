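Package: fosnet
Title: Brain-Wide Immediate Early Gene Co-Activation Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Functional co-activation network analysis for brain-wide
    immediate early gene (Fos, Egr-1) mapping studies. Starting from
    region-by-subject activity tables, the package computes inter-regional
    correlation matrices, derives one-tailed significance thresholds, and
    builds functional networks from supra-threshold positive correlations.
    Network characterization includes segregation and integration metrics
    contrasted against degree-matched rewired null ensembles, Markov
    cluster partitions, hub identification by joint degree/betweenness
    percentile across threshold tiers, and resilience to random and
    targeted node attack. Between-group inference covers bootstrap
    contrasts of block mean correlations, permutation comparison of whole
    correlation matrices with false discovery rate control, and
    mean-centered task and seed partial least squares with permutation
    tests and bootstrap salience ratios. Synthetic cohort generators with
    planted factor structure provide ground truth for every stage.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
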