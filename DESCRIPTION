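Package: floradisp
Title: Morphological Disparity, Factor Associations and Latitudinal
    Gradients for Mixed-Type Trait Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify morphological disparity from taxa-by-character
    matrices mixing binary, unordered, ordered and continuous characters with
    missing and polymorphic cells. Computes Gower-type mean character
    difference distance matrices, mean pairwise dissimilarity (disparity) per
    group, distance-based one-way permutation ANOVA and pairwise
    central-tendency permutation tests aggregated over random resolutions of
    polymorphism, chi-squared association tests among ecological factor
    categories with Pearson-residual association networks embedded by
    non-metric multidimensional scaling, cluster membership and disparity
    contrasts, and latitudinal richness and disparity profiles with a
    richness-controlled resampling null. Includes a synthetic-data generator
    emulating the statistical structure of floral trait datasets so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
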