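Package: hlreg
Title: Hierarchical Linkage Regression for Blind Cluster-Number Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the intrinsic number of clusters in a multidimensional
    numeric dataset without labels, by regressing on a two-dimensional
    histogram of agglomerative linkage coordinates (hierarchical linkage
    regression, HLR). The regressor is a small feedforward neural network
    trained entirely on synthetic random-cluster data, so no empirical
    training data are required. Includes the synthetic cluster generator,
    linkage-coordinate featurization, a distance-only ablation featurizer,
    ensemble median-rounded inference, cluster-delta evaluation metrics
    (recall, precision, F1, macro F1, Jaccard and normalized Jaccard) with
    percentile-bootstrap confidence intervals, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    withr,
    optparse,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
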