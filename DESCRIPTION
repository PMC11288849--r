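Package: selstack
Title: Stacking Ensemble Learning for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection toolkit built around stacked generalization.
    Provides GBLUP with the VanRaden genomic relationship matrix, multivariate
    adaptive regression splines (degrees 1-3), random forest and quantile
    regression forest base learners, an EM-REML fit of a multi-year
    progeny-trial mixed model with adjusted phenotypes, four level-one
    metadata constructions, six meta-learners including a two-kernel GBLUP,
    a repeated-holdout evaluation protocol with predictive ability, mean
    squared error, Spearman and top-decile agreement reports, and a
    family-structured population simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
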