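Package: amypet
Title: Amyloid-PET SUVR Quantification, Cut-Off Harmonization and Mixture
    Analysis on Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regional quantification of amyloid PET uptake images
    (standardized uptake value ratios over an atlas of bilateral grey-matter
    regions and a composite neocortical ratio), derivation of amyloid-positivity
    cut-offs by ROC analysis with closest-to-(0,1) optimal-point selection,
    harmonization of cut-offs across tracers through the regional-mean linear
    relation, Gaussian-mixture (EM) decomposition of composite-ratio
    distributions with BIC model selection, and cohort-level statistics
    (randomized covariate matching, two-way type III ANOVA, chi-squared,
    Spearman rank correlation, Cohen's kappa and d). A calibrated synthetic
    phantom and cohort generator provides seedable inputs with the group-wise
    distributional structure of published PIB and Florbetapir cohorts, so the
    full pipeline is testable without access to scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    car,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    nortest,
    optparse,
    withr
Config/testthat/edition: 3
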