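Package: elevflow
Title: Demographic Inference and Phenotype Association Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring rates and direction of gene flow among
    populations arrayed along an elevational gradient, built around biallelic
    SNP data. Provides VCF genotype import with minor-allele-frequency
    filtering and Hardy-Weinberg imputation, Nei-Chesser diversity and
    differentiation statistics (Hs, Ht, Fst, Fis, Jost's D), a structured
    coalescent simulator for five spatial gene-flow models (downslope, upslope,
    stepping stone, island, source-sink), approximate Bayesian computation for
    model selection with cross-validation, goodness-of-fit and parameter
    estimation, composite-likelihood inference from the folded site-frequency
    spectrum with parametric bootstrap, Mantel tests of trait-predictor
    association, and Pianka phenological-overlap metrics from weekly survey
    counts. Includes generators for synthetic genotype, survey and trait data
    so the whole pipeline can be exercised without field data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    nnet,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
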