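Package: repsim
Title: Representational Similarity Analysis with Variance Partitioning
    and Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) of
    condition-by-voxel fMRI response patterns. Builds representational
    dissimilarity matrices (RDMs, 1 - Pearson correlation) from model
    representations, behavioral rating counts, and motion-energy features;
    compares them to neural RDMs from volumetric searchlights and regions
    of interest; partitions unique variance between competing models with
    semi-partial Spearman correlations; performs group-level sign-flip
    permutation inference with false-discovery-rate control and z-map
    export; estimates split-half reliability and Spearman-Brown noise
    ceilings; runs time-resolved window analyses with repeated-measures
    ANOVA; selects decorrelated stimulus subsets; and generates synthetic
    multi-subject pattern datasets with planted representational geometry
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
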