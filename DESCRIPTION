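Package: pepnet
Title: Peptide-Level Bayesian Elastic-Net Models for Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential protein and PTM-site quantification from label-free
    peptide-ion intensity tables. Fits a hierarchical peptide-level linear
    model per protein (peptide, treatment, donor main effects plus
    peptide-by-treatment and peptide-by-donor interactions) with a
    confidence-weighted Bayesian elastic-net Gibbs sampler, in which
    observation weights blend a robust redescending residual weight with the
    identification confidence of each peptide ion, so that confidently
    identified outliers retain their influence. Residual variances are
    stabilised by empirical-Bayes moderation and treatment effects tested
    with moderated t-statistics under Benjamini-Hochberg control. PTM
    site-occupancy fold changes are read off the peptide-by-treatment
    interaction terms. Companion tools cover pathway-level linear models on
    protein fold changes, Gaussian fits to fold-change distributions,
    transcript-protein correlation, time-course K-means clustering with
    silhouette-based cluster-count selection, per-cell morphometry models
    with donor adjustment, log-log scaling regressions, and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Biostrings,
    fgsea,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
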