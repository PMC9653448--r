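Package: xspecies
Title: Cross-Species Cortical Cell-Type Comparison and Patch-Clamp Feature
    Extraction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing cortical cell types across primate and rodent
    single-cell RNA-seq datasets and for extracting intrinsic
    electrophysiological features from Patch-seq current-clamp recordings.
    Implements counts-per-10k normalization, log2 transformation and per-gene
    z-scoring; quality-control filters on detected features and mitochondrial
    content; per-cluster subsampling; one-to-one ortholog restriction; a
    co-clustering overlap statistic for cross-species cell-type homology;
    gene-set Spearman correlation of collapsed class-level z-score profiles
    with Kruskal-Wallis and Dunn post-hoc comparison of correlation
    distributions; fold-change flagging and regression-residual outlier genes;
    extraction of fourteen action-potential and passive membrane features from
    step-protocol voltage sweeps; and seeded synthetic-data generators (negative
    binomial multi-species count matrices with known divergence structure, and
    analytic voltage sweeps with known feature values) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, Electrophysiology, Normalization,
    QualityControl
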