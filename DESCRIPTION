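Package: expomap
Title: Exposure-Immunome-Omics Association and Mediation Pipeline
Version: 0.1.0
Authors@R:
    person("THPA", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping lifestyle and environmental
    exposures onto the human immunome through multi-omic data: quality
    control and transformation of immunophenotype, exposure and omics
    tables (skewness-gated outlier removal, mixed-model day-batch
    correction, rank-based inverse normal transformation, k-nearest
    neighbour imputation, plant-based diet index scoring); PERMANOVA
    variance decomposition of the immunome over exposures with FDR
    screening and redundancy pruning; exposure-wide association with
    covariate-adjusted linear models, likelihood-ratio tests, resampling
    stability, stratified, sensitivity and seasonal (cosinor) analyses;
    composite-exposure latent variables via thresholded Spearman
    correlation, Ward clustering and PLS path modelling; bidirectional
    causal mediation with bootstrap average causal mediation effects and
    direction classification; and mediation-proportion-weighted
    transcriptomic and metabolomic indexes. A seeded synthetic-cohort
    generator emulates the cohort structure every stage assumes and
    carries the ground truth used by the parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
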