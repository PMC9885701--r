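Package: oncosig
Title: Mutation-Anchored Onco-Signature Derivation and Single-Sample
    Enrichment Scoring for Tumor Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives mutation-anchored expression signatures
    ("onco-signatures") from a tumor cohort by binarizing tumor expression
    against a negative-binomial reference fitted on normal samples,
    counting recurrent dysregulation across mutated samples, selecting
    genes above the 98th percentile of the support distribution and
    keeping unique markers. Signatures are scored per sample with a
    competitive single-sample Mann-Whitney-Wilcoxon gene-set test
    (normalized enrichment score, NES), screened for survival association
    with univariate Cox regression, and used to cluster samples
    (Ward.D2). Includes cluster characterization (rank-sum differential
    expression, BH FDR, promoter-window PWM motif scanning) and a
    synthetic cohort generator with planted drivers, subtypes and
    survival structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    SummarizedExperiment,
    S4Vectors,
    yaml,
    knitr
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Survival, Clustering,
    GeneSetEnrichment, MotifDiscovery
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'binarize.R'
    'characterize.R'
    'coerce.R'
    'enrichment.R'
    'io.R'
    'oncosig-package.R'
    'pipeline.R'
    'promoters.R'
    'signatures.R'
    'simulate.R'
    'survival.R'
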