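Package: metacms
Title: Consensus Molecular Subtype Classification for Colorectal Cancer Liver Metastases
Version: 0.1.0
Authors@R: person("metacms", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Translates consensus molecular subtype (CMS) classification of
    colorectal cancer to bulk expression profiles of liver metastases.
    Estimates a per-sample hepatocyte "liver background" proportion from
    marker genes and regresses it out, selects cancer-cell-intrinsic
    features from microenvironment-free reference profiles, trains and
    applies a nearest-shrunken-centroids subtype classifier with
    posterior-probability confidence gating (optionally distilled to a
    random forest that needs no background adjustment), projects metastases
    onto principal components fitted on primary tumors, scores single-sample
    gene sets with a rank statistic, and quantifies intra-patient
    inter-lesion subtype heterogeneity including worst-subtype patient
    stratification. Ships a synthetic-cohort generator providing ground
    truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
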