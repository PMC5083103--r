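Package: adjSecretome
Title: Adjuvant-Stimulated Monocyte Secretome Analysis from Spectral Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free spectral-count analysis of adjuvant-stimulated human
    monocyte secretomes in a paired newborn/adult design. Implements
    half-minimum imputation, total-count and protein-length normalization,
    fold-change summaries, the inclusion/exclusion filters and
    condition-overlap accounting used for secretome Venn summaries, two-way
    hierarchical clustering (Pearson distance, Ward's minimum-variance
    aggregation), paired Poisson count-model differential abundance with
    empirical-Bayes moderated Z statistics and Benjamini-Hochberg FDR,
    Fisher's-exact gene-set over-representation (including the EASE
    variant), an exact nonparametric test kernel (signed-rank, rank-sum,
    Fisher, Kendall tau-b), and a secretome-to-transcriptome concordance
    procedure against a fixed gene background. A synthetic-data generator
    with known ground truth emulates the paired spectral-count and
    multi-timepoint expression designs so every stage is testable offline.
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
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression,
    Clustering, GeneSetEnrichment
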