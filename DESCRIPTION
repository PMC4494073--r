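Package: coralAcclim
Title: Transcriptome and Bleaching-Phenotype Analysis of Short-Term Thermal
    Acclimation in Corals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing short-term thermal-acclimation experiments in
    reef-building corals from a gene-by-sample read-count matrix and a
    factorial design (acclimation treatment x acclimation day x acute-stress
    condition). Implements abundance filtering, median-of-ratios
    normalization, PCA-based outlier flagging, per-gene two-factor
    permutational ANOVA with Benjamini-Hochberg FDR, co-expression clustering
    with eigengene summaries, a gene-set resampling null for cluster-level
    heat-stress responses, quantification of transcriptional dampening versus
    frontloading, and chlorophyll-a bleaching quantification with wax-dip
    surface-area calibration. A negative-binomial simulator generates complete
    synthetic experiments with known ground truth so every stage of the
    pipeline can be validated against planted signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    DESeq2,
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Normalization, Clustering,
    DifferentialExpression
RoxygenNote: 7.3.3
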