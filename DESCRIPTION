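Package: multifold
Title: Multi-Condition Probing-Directed RNA Secondary Structure Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts dominant RNA secondary structure models by stochastic
    sampling of pseudo-Boltzmann ensembles guided by one or more chemical
    probing reactivity profiles (SHAPE, DMS, CMCT), clustering the sampled
    structures across probing conditions, and returning maximum expected
    accuracy centroids of Pareto-optimal clusters scored by stability and
    cross-condition support. Also provides ensemble-distance comparison of
    probing conditions via base-pair probability dot plots, box-plot
    reactivity normalization and reagent masking, pseudoknot removal,
    prediction quality metrics (MCC, geometric mean), and a synthetic
    reactivity-profile generator for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    rlang,
    withr,
    ggplot2,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
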