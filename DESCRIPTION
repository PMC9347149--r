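Package: tmbias
Title: Bias and Depth Inconsistency in Tumour Mutation Burden Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies two statistical biases in tumour mutation burden (TMB)
    estimation from sequencing data: the upward bias of the observed mutant
    read proportion under zero- and threshold-truncation of the binomial read
    count, and the threshold-crossing bias that arises when the mutant allele
    frequency spectrum has substantial mass near the counting threshold.
    Provides truncated-binomial distributions with Fisher's maximum-likelihood
    frequency estimator, a beta/beta-binomial theory of the expected versus
    true above-threshold mutation count and its relative error, a synthetic
    tumour sequencing simulator (clonal plus beta-distributed subclonal
    frequencies, per-site depth, purity scaling, read-level down-sampling),
    threshold-counting and spectrum-model TMB estimators, and scripted
    experiments that reproduce the bias, down-sampling and depth-correlation
    analyses on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'tmbias-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'trunc-binom.R'
    'spectrum-model.R'
    'synthetic-data.R'
    'io.R'
    'tmb-pipeline.R'
    'spectrum-fit.R'
    'experiments.R'
    'show-methods.R'
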