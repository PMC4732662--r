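Package: tcrossgs
Title: Genomic Prediction of Testcross Performance with RR-BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection toolkit for hybrid breeding programmes that
    evaluate candidate parental (pollinator) lines through testcrosses with a
    small set of testers over multiple field locations. Provides SNP panel
    quality control (missingness, monomorphism and minor-allele-frequency
    filters with mean imputation), population-structure inference (Rogers
    genetic distances, principal coordinate analysis, K-means clustering with
    Calinski-Harabasz model selection), phenotype modelling for unreplicated
    multi-location trials (best linear unbiased estimates, REML variance
    components, broad-sense heritability, general combining ability),
    a ridge-regression BLUP mixed model with REML estimation of the
    variance ratio by spectral decomposition, and a repeated random
    cross-validation engine covering whole-population, within-subpopulation,
    cross-subpopulation and structure-covariate prediction scenarios,
    including training-size sweeps. A configurable generator of structured
    inbred genotypes and testcross phenotypes with known truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
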