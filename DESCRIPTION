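Package: lesionlatent
Title: Succinct Latent Representations of Ischaemic Stroke Lesion Anatomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns succinct representations of binary stroke lesion masks
    registered to a common stereotactic grid (a 50-dimensional non-negative
    matrix factorisation, a 2-dimensional t-SNE embedding refined by
    structure-aware filtering, and a categorial representation from Ward
    clustering with archetype centroid images), constructs synthetic
    parcellation-based lesion-deficit ground truths by a regional damage
    threshold rule, and benchmarks the predictive fidelity of each
    representation with balanced resampling and nested cross-validated
    gradient boosting, summarised with confidence intervals and two-way
    ANOVA. Includes a hierarchical vascular-territory lesion simulator so
    the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xgboost
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
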