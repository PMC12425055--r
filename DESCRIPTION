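Package: mpscore
Title: Methylation Population Scores for Population Structure in EWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised estimation of population structure from epigenome-wide
    CpG methylation. Trains sparse methylation population scores (MPSs) that
    predict genetic principal components via a meta-analyzed covariate-adjusted
    association scan (inverse-variance fixed effects across cohorts,
    Benjamini-Hochberg selection) followed by two-stage weighted Lasso
    regression, exports portable CpG weight files, applies them to new
    methylation matrices, and evaluates how well MPS adjustment controls
    genomic inflation in epigenome-wide association studies compared with
    genetic principal components. Includes a multi-cohort synthetic-data
    generator (Balding-Nichols genotypes with Dirichlet admixture, mQTL-like
    ancestry effects on CpG beta values, confounding covariates) so the whole
    pipeline runs without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
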