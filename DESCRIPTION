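Package: intermod
Title: Integrative Transcriptome-Metabolome Co-Expression Modules,
    Regulatory Networks, and Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of factorial multi-omics
    experiments in which transcript and metabolite abundances are profiled
    across crossed design factors (variety, location, developmental stage).
    Provides EM-based decomposition of the coefficient-of-variation
    distribution into low- and high-variability components, per-feature
    full factorial ANOVA with Benjamini-Hochberg correction and a fold
    change magnitude filter, weighted co-expression module detection with
    topological overlap, module eigengenes and kME statistics, mutual
    information regulator-target networks with data-processing-inequality
    pruning, two-way Pearson correlation integration of gene and metabolite
    modules, Fisher combined-probability gene prioritization, and
    hypergeometric pathway enrichment. A synthetic-data generator plants
    recoverable ground truth (modules, differential features, cross-layer
    couplings, a regulator with targets) so every stage is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'coexpression.R'
    'dataio.R'
    'enrichment.R'
    'factorialDE.R'
    'integration.R'
    'miNetwork.R'
    'prioritization.R'
    'varianceFilter.R'
    'simulate.R'
    'pipeline.R'
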