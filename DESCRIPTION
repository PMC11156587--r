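Package: admixdeconv
Title: Decomposing Ancestry-Associated Gene Expression into Genetic and
    Environmental Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how genetic ancestry shapes gene
    expression in admixed cohorts. Provides a synthetic admixed-cohort
    generator with known genetic and environmental ground truth (genotypes,
    ancestry tracts, multi-region expression counts, WGBS-style methylation),
    ancestry-informative marker selection and supervised maximum-likelihood
    global-ancestry estimation, per-region ancestry differential expression,
    an empirical-Bayes multivariate adaptive-shrinkage engine with local
    false sign rates, cis-eQTL mapping with permutation-based top
    associations and Storey q-values, elastic-net transcriptome imputation
    for quantifying the genetic component of ancestry effects, variably
    methylated region calling with the P_ST partial-R2 environmental
    statistic, and cross-region sharing and enrichment summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    vcfR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
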