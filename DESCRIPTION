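Package: mbMediate
Title: Mediation Analysis of Disease Effects Through Gut Microbiome
    Alterations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how much of the effect of a binary exposure (such as
    Parkinson's disease) on a rare binary outcome (such as underweight, BMI
    below 18.5) is mediated by gut-microbiome composition. Implements the
    difference-of-coefficients estimator with high-dimensional microbial
    mediators: a quasi-binomial logistic total-effect model, a ridge-penalized
    quasi-binomial direct-effect model in which only mediator coefficients are
    penalized, per-taxon linear exposure-to-mediator models, proportion
    mediated, and joint-significance (max-p) mediation tests. Also provides
    the surrounding cohort workflow: feature-table input/output and sample
    alignment, relative-abundance normalization, prevalence filtering,
    taxonomic aggregation, alpha and beta diversity with ANOVA and PERMANOVA
    group tests, demographic comparison tables, per-taxon Wilcoxon volcano
    statistics, and a synthetic-cohort generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    phyloseq,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Regression, StatisticalMethod
RoxygenNote: 7.3.3
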