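# floradisp

Morphological disparity, factor associations and latitudinal gradients for
mixed-type trait matrices.

`floradisp` is an R package plus analysis workflow for quantifying the
*morphological diversity* (disparity) of a set of taxa — typically species
scored for floral characters — and relating it to ecology and geography. It
is aimed at comparative morphologists working with taxa × characters
matrices that mix binary, unordered categorical, ordered categorical and
continuous characters, and that contain missing and polymorphic cells.

## What it computes

**Distances and disparity.** For a pair of taxa the *mean character
difference* is a Gower-type index over the characters scored in both:

    D(i, j) = (1 / n_shared) * Σ_k d_k

with `d_k` a 0/1 mismatch for binary and unordered characters,
`|rank_i − rank_j| / range_span` for ordered characters and
`|x_i − x_j| / range_span` for continuous ones, so `D ∈ [0, 1]`. The
disparity of a group is the *mean pairwise dissimilarity* `D̄`, the mean of
all within-group `D` values (reported ± the SD of those pairwise values).
Polymorphic cells are resolved by uniform random sampling before every
distance computation.

**Inference.** Disparity is compared across the categories of an
ecological factor (growth form, habitat, climate, region) with a
distance-based one-way permutation ANOVA
(`F = (SS_among/(a−1)) / (SS_within/(N−a))` on squared distances, null from
random reassignment of taxa to groups) and pairwise central-tendency
permutation tests (statistic `T` = difference of the two groups' mean
within-group `D`, Bonferroni-corrected). Because the grouping factor itself
is polymorphic for some species, every test is repeated over random
resolutions of the factor and reported as mean ± SD.

**Associations.** Pairwise factor associations are tested with Pearson
chi-squared tests; association strength and direction come from the
Pearson residuals `(O − E)/√E`, which also drive an NMDS "association
network" embedding (Bray–Curtis on shifted residual profiles) and the
identification of clusters of positively associated categories, whose
disparity can then be contrasted.

**Latitudinal gradients.** Occurrence records are binned into 18
half-open 10° latitude bands; per-bin species richness and disparity are
regressed on distance from the Equator, and a richness-controlled
resampling null asks whether per-bin disparity exceeds what equally sized
random species sets would give.

**Synthetic data.** `synth_spec()` / `gen_dataset()` generate matched
morphological, ecological and occurrence tables with tunable missingness,
polymorphism, planted category associations, group-specific trait
dispersion and climate-linked latitudinal ranges, so the whole pipeline is
testable end to end without any downloads.

## Worked example

```r
library(floradisp)

ds <- gen_dataset(synth_spec(seed = 20260928))   # 380 taxa x 36 characters
dm <- distance_matrix(ds$m, seed = 1)
disparity_table(disparity_by_category(dm, ds$ft, "climate"))
```

```
   category n_taxa n_pairs      mean         sd
1  tropical    161   12880 0.3567698 0.08332768
2      arid     49    1176 0.2887619 0.13951767
3 temperate    114    6441 0.2599717 0.09093828
4      cold     70    2415 0.2060757 0.10019469
5     polar     39     741 0.2886888 0.13402391
```

The planted high-dispersion tropical category shows the highest `D̄`
(0.357 ± 0.083 over 161 species); `n_pairs` counts the within-category
taxon pairs the estimate averages over. The full workflow — simulation,
descriptive disparity, permutation tests, association network, cluster
contrast, latitudinal profile — is run by the numbered drivers:

```sh
Rscript analysis/01_simulate.R      # writes results/inputs/
Rscript analysis/02_disparity.R     # results/disparity.tsv
Rscript analysis/03_inference.R     # results/tests_anova.tsv, tests_posthoc.tsv
Rscript analysis/04_associations.R  # results/associations.tsv, edges, NMDS
Rscript analysis/05_clusters.R      # results/cluster_contrast.json
Rscript analysis/06_latitude.R      # results/latitude_profile.tsv, stats
```

On the default study dataset these report, e.g., a latitudinal disparity
profile peaking at 0.377 in the [−20°, −10°) band, richness and disparity
both decreasing with distance from the Equator (Pearson r = −0.94 and
−0.91), and a significantly higher disparity for the tropical-forest-tree
association cluster than for its temperate counterpart (|T| = 0.064,
P = 0 at 9999 permutations).

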