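Package: agrioutlier
Title: Outlier Detection for Regional Agronomic Yield Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects anomalous records in regional crop-yield tables with six
    unsupervised procedures: iterative interquartile-range filtering, a
    Mahalanobis elliptic envelope, a PCA-plus-Euclidean-distance envelope,
    isolation forest, one-class support vector machine, truncated-SVD
    reconstruction residuals, and spatial multiview similarity scoring.
    Includes a synthetic agronomic-data generator with ground-truth labels
    for three mechanistically distinct outlier kinds (global, spatial,
    multiview-inconsistent) and a confusion-matrix benchmark harness
    reporting precision, recall, F1 and accuracy per method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
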