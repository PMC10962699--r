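Package: tripletrsa
Title: Odd-One-Out Triplet Similarity, Representational Similarity, and
    Activation-Overlap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for behavioral and neural representational
    similarity analysis of object-category selectivity. Aggregates
    odd-one-out triplet judgments and 1-7 Likert ratings into
    representational dissimilarity matrices (RDMs) with split-half
    reliability and Spearman-Brown correction; builds dummy-coded model
    RDMs for a counterbalanced 48-stimulus design; compares RDMs by rank
    correlation with leave-one-out noise ceilings and nonmetric
    multidimensional scaling; defines regions of interest from
    statistical maps with an adaptive threshold and cluster rule;
    quantifies spatial overlap of selectivity maps via the Jaccard index
    and top-N voxel curves; and partitions explained RDM variance across
    three predictors by commonality analysis with a row-shuffle
    permutation test. Includes generators for synthetic triplet, rating,
    voxel-pattern, and statistical-map data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
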