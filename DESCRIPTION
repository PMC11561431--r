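Package: detana
Title: Determinant Analysis of Behavioral Intention from Likert Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying and prioritizing determinants of a
    dichotomous behavioral intention from 5-point Likert questionnaire data.
    Screens candidate determinants with a random-forest classifier and
    out-of-bag permutation importance (increase in misclassification
    probability), groups the selected determinants by average-linkage
    hierarchical clustering on a Spearman-correlation dissimilarity with a
    compactness/separation rule for the number of clusters, and ranks items
    and clusters for intervention by Cohen's d and the Potential for Change
    Index, with CIBER-style visualization. Includes a latent-factor
    generator of synthetic Likert data with planted cluster structure and
    intention signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    grid,
    gtable
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
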