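Package: crtmerge
Title: Design and Analysis of Cluster Randomised Trials with Merging Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the consequences of post-randomisation
    cluster merging in two-arm cluster randomised controlled trials with a
    continuous outcome.  Provides closed-form sample-size and power
    calculations that account for the cluster-size variability and
    allocation imbalance created when pairs of clusters combine, a Monte
    Carlo simulator of homogeneous (same-arm) and heterogeneous (cross-arm)
    merges under several analysis strategies, and a fast profiled-REML
    fitter for the two-level random-intercept model used to analyse the
    simulated trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
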