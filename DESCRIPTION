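Package: pathwayGWAS
Title: Pathway-Based Association Analysis for Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene set enrichment analysis for case-control genome-wide
    association studies. Implements per-SNP quality control (call rate,
    Hardy-Weinberg exact test, minor allele frequency), additive-coded
    logistic Wald tests with covariates, genomic-control lambda adjustment,
    gene-level min-p statistics, a weighted Kolmogorov-Smirnov-like
    running-sum enrichment score with phenotype-permutation null
    distribution and normalized enrichment scores, plus a synthetic
    case-control cohort generator with known planted effects for
    end-to-end validation. Reads and writes PLINK text PED/MAP, GMT gene
    sets and tab-separated covariate and annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociationStudies, SNP, GeneSetEnrichment, Pathways,
    StatisticalMethod
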