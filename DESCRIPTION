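Package: metabotree
Title: Two-Stage Hierarchical Classification of Lung-Cancer Type from
    Metabolite Molecular Descriptors
Version: 0.1.0
Authors@R:
    person("Metabotree", "Developers", email = "metabotree@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for classifying lung-cancer type (small-cell
    carcinoma versus the non-small-cell subtypes adenocarcinoma and squamous
    cell carcinoma) from molecular descriptors of candidate metabolite
    biomarkers.  Implements significance and fold-change filtering of
    metabolite tables, min-max normalization, information-gain feature
    selection over discretized descriptors, dimensionality reduction by PCA
    (covariance eigendecomposition) and by t-SNE written from first
    principles, small feedforward neural-network classifiers arranged as a
    two-stage tree (NS/SC then AD/SQ), the class-fraction-weighted overall
    accuracy combiner, stratified k-fold cross-validation and
    independent-set evaluation protocols, a naive multiclass baseline, and a
    seeded synthetic-data generator emulating hierarchically labeled
    clusters in high-dimensional descriptor space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
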