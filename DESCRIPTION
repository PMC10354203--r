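Package: ethomotif
Title: Supervised and Unsupervised Behavioral Motif Analysis for
    Markerless Pose Tracking of Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts markerless pose-estimation time series (DeepLabCut-style
    tracking tables) of one or two mice into behavioral readouts. Provides
    trajectory preprocessing (Savitzky-Golay smoothing, likelihood-based
    quality flagging, iterative ridge imputation, jump correction), kinematic
    feature extraction (egocentric alignment, distances, angles, body areas,
    time derivatives), rule-based annotation of individual and dyadic
    social behaviors with Kleinberg burst smoothing, a trainable
    stopped-and-huddled classifier harness, a mixture-of-Gaussians
    variational graph embedding for unsupervised time-aware behavioral
    clustering, and downstream statistics: global cluster-usage embeddings,
    Wasserstein-distance habituation binning, cluster enrichment tests,
    Markov-chain behavioral entropy, permutation-SHAP cluster
    explainability, and composite directional Z-scores. A synthetic-cohort
    generator with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
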