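Package: placebocolor
Title: Color Matching of Medicinal Granule Placebos by Cluster-Then-Regress
    Pigment Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the doses of four food pigments (caramel, lemon yellow,
    carmine, indigo) that tint an inert excipient base to visually match the
    measured RGB color of a medicinal granule powder, for placebo manufacture
    in blinded clinical trials. Fits a hierarchical model on a library of
    pigment/color pairs: standardized RGB colors are k-means clustered (k
    chosen by silhouette with an elbow diagnostic), then per-cluster regression
    models (linear, ridge, support-vector, random-forest and gradient-boosting)
    compete under repeated 5-fold cross-validation with grid search, and the
    per-cluster winner inverts color to pigment doses. Includes CIELAB delta-E
    and RGB cosine similarity evaluation with perceptibility bands, exact
    Shapley attribution of channel contributions, circular-ROI mean-color
    extraction with whiteboard calibration, and a Beer-Lambert-style forward
    mixing simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    cluster,
    e1071,
    ranger,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
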