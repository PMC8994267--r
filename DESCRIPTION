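Package: movescape
Title: State-Dependent Movement Models, Step Selection, and Simulated
    Landscape Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits two-state hidden Markov movement models with
    covariate-dependent transition probabilities to GPS telemetry (gamma
    step lengths, von Mises turn angles), builds state-interacted step
    selection functions by conditional logistic regression with
    cluster-robust variance and QIC backward selection, simulates
    SSF-weighted individual movement paths under reference, current, and
    future development scenarios, and summarises the resulting path
    ensembles as utilization distributions, equal-area habitat bins, and
    Merriam connectivity metrics (patch traversals and transect
    crossings). Includes a synthetic valley-landscape and labelled-track
    generator so every fitting stage can be checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
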