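Package: heterASE
Title: Allele-Specific Expression, Expression Inheritance and Transcriptomic
    Entropy in F1 Hybrids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the transcriptomic basis of heterosis in
    F1 hybrid crops from trio (female x male x hybrid) designs. Implements
    parent-guided phasing of hybrid heterozygous SNPs, a Bayesian binomial
    mixed model for population-level allele-specific expression (ASE) tested
    against a dataset-median null, per-hybrid haplotype ASE with cis/trans
    regulatory classification, additive/non-additive expression-inheritance
    calling by BIC model comparison on negative-binomial fits, deleterious
    allele complementation and suppression scoring, Shannon-entropy profiling
    of transcriptomic plasticity, and phenotype heterosis/genetic-gain
    statistics. A synthetic-data module generates all pipeline inputs with
    known ground truth so every stage can be exercised and validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    DESeq2,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), vcfR, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Bayesian, Genetics
RoxygenNote: 7.3.3
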