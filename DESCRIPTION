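Package: endotwin
Title: Twin-Based Genetic Parcellation and Endophenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component twin modelling and genetically informed
    parcellation for endophenotype discovery. Provides full-information
    maximum-likelihood univariate and bivariate AE models on twin/sibling
    families (heritability, genetic and environmental correlations,
    likelihood-ratio tests, simulation-based power), fuzzy clustering of
    vertex-wise genetic-correlation matrices with silhouette-based selection
    of the number of clusters, kinship-aware REML mixed models testing
    nonlinear (natural-spline) associations between cortical phenotypes and
    a continuous symptom score, eigenvalue-based effective numbers of
    independent tests with Sidak family-wise error control, and a synthetic
    twin-cohort generator with planted genetic architecture so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
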