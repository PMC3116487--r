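Package: profileANOVA
Title: Cluster-Based ANOVA for Multi-Factorial MALDI-TOF MS Profiling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete biomarker-discovery workflow for multi-factorial
    MALDI-TOF mass-spectrometry profiling studies. Raw continuous spectra are
    pre-processed (log transformation, median smoothing, morphological tophat
    baseline correction, reference-peak index alignment, continuous-wavelet
    peak picking) into a variance-stabilized peaks-by-profiles intensity
    matrix. Per-peak significance for each experimental factor and a
    genotype-by-diet interaction is obtained from nested linear-model F-tests.
    Peak redundancy caused by shared parent proteins is exploited through
    average-linkage clustering on the 1 minus Pearson-correlation distance,
    with ANOVA p-values attached to every dendrogram node, and drives a
    cluster-representative feature-selection strategy for decision-tree
    classification, benchmarked against a plain ANOVA filter and an ant-colony
    wrapper. A seeded synthetic-data generator emulating a genotype-by-diet-
    by-week plasma-profiling study provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), methods, SummarizedExperiment
Imports: stats, utils, tools, S4Vectors, ape, rpart, jsonlite, yaml
Suggests: testthat (>= 3.0.0), mzR, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'profileANOVA-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'preprocess.R'
    'cwt.R'
    'anova.R'
    'redundancy.R'
    'selection.R'
    'io.R'
    'pipeline.R'
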