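Package: painstrat
Title: Data-Driven Biopsychosocial Sub-Grouping of Chronic Low Back Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An unsupervised stratification pipeline for multidimensional
    (nervous system, spinal tissue, psychosocial) feature tables from
    case-control chronic low back pain studies. Screens variables with
    between-group t-tests and Benjamini-Hochberg false-discovery-rate
    control, filters multicollinearity, weights features with a random
    forest, ranks them within cases by the Laplacian score, selects the
    feature count and cluster number by an incremental cluster-validity
    scan (Calinski-Harabasz, Davies-Bouldin, silhouette), derives fuzzy
    c-means sub-groups, benchmarks their re-identifiability with four
    classifiers under repeated stratified holdout, and characterises the
    sub-groups post hoc (ANOVA with Tukey HSD, Pearson correlations,
    chi-square). Includes a synthetic-cohort generator and a toolkit for
    the derived MRI and sensory-testing variables (multi-echo T2, Dixon
    fat fraction, slice-scaled volumes, temporal-summation and
    exercise-induced-hypoalgesia change scores).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
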