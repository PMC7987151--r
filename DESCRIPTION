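Package: crowdscreen
Title: Worker Screening and Bias Amplification in Crowdsolved Judgements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for nominal-group "crowdsolving":
    generates synthetic worker pools with a latent reasoning trait and
    lure-dominated bias items, scores multi-subtest reasoning batteries
    (Cognitive Reflection Test, Raven's matrices short form,
    heuristics-and-biases items, syllogistic reasoning), screens workers by
    CRT performance, aggregates nominal-group answers by plurality vote with
    random tie-breaking across group sizes, and compares the simulated
    accuracy-versus-group-size curves against exact Condorcet-style plurality
    probabilities under both iid (multinomial) and finite-pool
    (multivariate hypergeometric) voting. Includes the accompanying
    descriptive and inferential layer: Welch t tests, nonparametric
    correlations, per-item chi-square screening contrasts, and hierarchical
    regressions with R-squared change statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
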