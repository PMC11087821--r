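Package: draphnet
Title: Bilinear Affinity Regression Linking Drug Molecular Profiles to the Disease Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised bilinear ("affinity regression") modelling of binary
    drug-phenotype associations from two molecular feature spaces: a
    drug-by-assay-endpoint matrix with missing entries (ToxCast-style hit
    fractions) and a gene-by-phenotype matrix of signed transcriptome-wide
    association z-scores (PhenomeXcan-style). Provides soft-thresholded
    iterative SVD (SoftImpute) completion of the endpoint matrix with
    entry-holdout cross-validation, Kronecker-trick reduced-rank lasso
    logistic regression for the drug-phenotype interaction matrix,
    projections of drugs onto phenome and disease-genome spaces with
    permutation-based empirical p-values and Benjamini-Yekutieli
    correction, hypergeometric target-gene enrichment with permuted-target
    calibration, a drug-drug network built from significant disease-gene
    overlap with a weighted-sampling null and clique-based categorisation,
    cross-validated evaluation against a nearest-neighbour baseline, and a
    planted-truth synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
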