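Package: contoureval
Title: Geometric Evaluation of Target-Volume Contours and Delineation-Training Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates 3D binary segmentation masks against reference volumes
    with the standard battery of overlap and boundary-accuracy metrics (Dice,
    Jaccard conformity, inclusion, relative volume difference, average surface
    distance, percentile Hausdorff distance, centroid distance, volume), using
    an anisotropic Euclidean distance transform. Summarises interobserver
    variability (SD, CV, max/min volume ratio), runs paired pre/post
    comparisons with distribution-gated test selection and effect sizes
    (r = |Z|/sqrt(n), d = |t|/sqrt(n)), applies quality-control exclusion
    rules, and computes directionally adjusted Spearman correlations between
    Likert self-assessments and objective contour quality. Includes a
    synthetic contouring-cohort generator (perturbed reference volumes plus
    questionnaire responses) and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    rlang,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
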