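---
title: "Methods: disparity, association networks and latitudinal gradients in floradisp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disparity, association networks and latitudinal gradients in floradisp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floradisp)
```

`floradisp` quantifies the morphological diversity (*disparity*) of groups
of taxa from a mixed-type trait matrix and relates it to ecological factors
and latitude. This vignette is the package's account of the statistical
machinery: the models and conventions it commits to, the knobs that matter,
what the synthetic-data generator does and does not emulate, and the known
limitations. Everything numerical stated here is computed by the test suite
or by `scripts/acceptance.R`; nothing is asserted from memory.

## Data model

The central object is a taxa × characters matrix whose cells are *state
sets*: an empty set is a missing score, a singleton a monomorphic score, a
larger set a polymorphic one. Characters are typed as binary, unordered
categorical, ordered categorical, or continuous; continuous cells hold one
or more measurements (several measurements are treated as polymorphism like
any other multi-state cell). A parallel taxa × factors table assigns each
species to one or more categories of each ecological factor (growth form,
habitat, climate, region); multi-membership there is frequent and
biologically real — a species can grow in both temperate and cold zones.
Occurrence records are plain (species, latitude, longitude) triples, with
an optional per-species bounding-box filter standing in for manual
curation of non-native records.

On disk everything is delimited text with a header row and taxa in the
first column; polymorphic cells join their states with `/` and missing
cells are `?` (NEXUS-style conventions). Character definitions travel in a
sidecar table (`character_id`, `kind`, `states` joined by `|`, in rank
order for ordered characters). Writers and readers round-trip cell sets
exactly; continuous values are serialized with 17 significant digits for
that reason. When the morphological and factor tables disagree on taxa,
analyses use the intersection and say so.

## The distance and the disparity index

The pairwise dissimilarity is the *mean character difference*, a Gower-type
index: for characters scored in both taxa, binary and unordered characters
contribute a 0/1 mismatch, ordered characters the absolute rank difference
divided by the character's rank span, continuous characters the absolute
difference divided by the range; the pair's distance is the average of
these contributions, so it always lies in [0, 1]. Characters missing in
either taxon are excluded from numerator and denominator; a pair sharing no
scored character is flagged undefined rather than imputed.

Two scaling conventions are fixed deliberately:

* **Spans are dataset-wide.** `range_span` of ordered and continuous
  characters is recomputed from the whole matrix at load time and shared by
  every downstream comparison, so all groups live in a single morphospace
  and their disparities are comparable. A zero span contributes zero
  dissimilarity.
* **Ordered characters use rank differences** over the observed rank range
  (not unit steps along the full vocabulary). Where a vocabulary state is
  never observed, the span shrinks accordingly.

Group disparity `D̄` is the mean of all defined within-group pairwise
distances. The SD reported with it is the sample (n − 1) standard deviation
of those pairwise values — it describes the spread of the pairwise-distance
distribution, not a bootstrap error of the mean. `D̄` was chosen over
range-type indices because it is insensitive to group size: the expected
`D̄` of a random subsample equals the full-group value, which the tests
check directly (and which makes categories of very different sizes
comparable).

Polymorphism is handled by random resolution: before every distance-matrix
computation each polymorphic cell is replaced by one member of its state
set drawn uniformly, under an explicit seed. For descriptive disparity a
species belonging to several categories of a factor counts in each of
them; for the tests below it is resolved to exactly one category per
repetition, never duplicated.

## Permutation inference

Differences in `D̄` among the categories of one factor are tested with a
distance-based one-way permutation ANOVA. With `A = d²`,

* `SS_total = Σ_{i<j} d_ij² / N`,
* `SS_within = Σ_g Σ_{i<j∈g} d_ij² / n_g`,
* `F = (SS_among/(a−1)) / (SS_within/(N−a))`.

This is the standard pseudo-F partition of squared interpoint distances;
it reduces to the classical one-way ANOVA F for Euclidean distances on a
single variable, and it matches `vegan::adonis2` to machine precision
(both are verified in the tests). A permutation test is used instead of a
parametric ANOVA because every species contributes to many pairwise
distances, so the distance values are not independent. The null
distribution shuffles taxon identities of the distance matrix — equivalent
to assigning a random row of the morphological matrix to each species
without replacement — which preserves the multiset of distances exactly.

Numerical conventions worth stating:

* **p-value**: `#{F_perm ≥ F_obs} / n_perm` by default, so a
  never-attained statistic reports exactly 0; the `(count+1)/(n_perm+1)`
  variant is available via `p_convention = "plus-one"`. Rejecting at
  `p ≤ α` with the default convention gives an exactly nominal test
  (type-I error 0.050 in theory; 0.045–0.052 measured over 1000 null
  datasets in the acceptance checks).
* **Ties count toward the numerator.** A permuted statistic exactly equal
  to the observed one (including the two-sided `|T|` comparison below, and
  the infinite-F case of perfectly separated groups) increments the count.
  One useful identity the tests pin down: if *all* pairwise distances are
  equal, every grouping yields F = 1 exactly — each permutation ties and
  the p-value is 1.
* **Perfect separation** (`SS_within = 0`) reports `F = Inf`; permutations
  that happen to recreate the partition tie with it, so the smallest
  attainable p in a tiny instance is the recreation probability, while at
  realistic sizes p = 0.
* **Tiny categories** (fewer than 3 taxa after resolution) are dropped from
  tests with a warning; two-species categories carry a single pairwise
  distance and only destabilize the F.

Post-hoc comparisons use a central-tendency permutation statistic: for a
category pair, `T` is the difference of the two categories' mean
within-category pairwise distances, its null obtained by shuffling taxa
between the two categories only; p-values are two-sided on `|T|` and
Bonferroni-corrected across the pairs tested. The distance submatrix is put
in a canonical row order before permuting, so swapping the two groups flips
the sign of `T` and reproduces the identical p — the sampled test is
exactly symmetric, not just asymptotically.

Because the grouping factor itself contains multi-valued cells, every test
is repeated over `n_resolutions` random resolutions of the factor (and a
freshly resolved morphological matrix and distance matrix each time);
statistics and p-values are reported as mean ± SD across repetitions. When
neither table contains relevant polymorphism the repetitions would be
byte-identical, so a single run is performed and the SDs are exactly zero.
Per-resolution seeds are spawned deterministically from one base seed, so
any reported aggregate is reproducible from a single integer.

## Association networks

Whether categories of *different* factors co-occur more or less often than
expected is tested per factor pair with a Pearson chi-squared test (no
continuity correction, expected counts from the product of marginals).
Counting follows the Cartesian-product rule: a taxon contributes one count
to every combination of its category sets, which keeps the table
deterministic under multi-membership; taxa missing either factor are
excluded. Sparse categories can be merged (e.g. polar into cold) or
excluded (e.g. a two-species category) before counting; a zero marginal is
a hard error suggesting exactly that. Association strength and direction
come from the Pearson residuals `(O − E)/√E`.

For visualization and cluster finding, each category is described by the
profile of its residuals against all categories of the other factors.
Residuals are signed, and Bray–Curtis dissimilarity is only defined for
non-negative data, so profiles are shifted by the global minimum first;
distances are computed over the profile coordinates defined for both
categories (residuals within a factor do not exist, so the comparison set
varies by pair — the Bray–Curtis step is hand-rolled for this reason). The
resulting category × category distance matrix is embedded in two dimensions
by non-metric multidimensional scaling (monotone regression, Kruskal
stress-1, best of `n_starts` random starts through `vegan::metaMDS`,
deterministic under a seed); coordinates are centred and scaled to unit RMS
point norm. Significant associations (factor-pair test `p < alpha`,
`|PR| ≥ pr_threshold`, default 2 ≈ a standard-normal residual at the 5%
level) become signed edges; *clusters* of mutually associated categories
are the connected components of the positive edges, and a manual cluster
specification is accepted wherever a derived one is.

A cluster over factor categories selects taxa by intersection across
constrained factors and union within a factor ("tropical or temperate
shrubs"), excluding taxa missing any constrained factor. Two clusters are
contrasted with the same central-tendency permutation test (overlapping
taxa removed from both sides first).

## Latitudinal gradients

Occurrence records are binned into 18 half-open 10° bands covering
[−90°, 90°) (a record at exactly +90° joins the top band). Presence is
record-based by default — a species is present where it has records, with
no interpolation between its extremes — because automated occurrence data
cannot support more; an optional `range_fill` mode marks every band between
a species' extreme records as present, approximating range maps. Per-band
richness and disparity (the `D̄` of the present species; undefined below
two) are then related to the absolute band midpoint — distance from the
Equator — with Pearson correlations and ordinary least squares, optionally
excluding species-poor bands, whose `D̄` estimates are noisy.

The decoupling question — is high tropical disparity merely a by-product of
high tropical richness? — is answered with a richness-controlled null: for
each band with `n_b ≥ 2` species, many uniform random sets of exactly
`n_b` species are drawn from the full pool and their `D̄` computed; the
observed band value is located in that distribution (95% envelope and a
two-sided tie-inclusive empirical p). If disparity only tracked richness,
observed values would sit inside the envelope. One caveat the tests make
explicit: adjacent bands share most of their species, so band-level
verdicts are strongly correlated — a single chance fluctuation in a shared
species set can flag several neighbouring bands at once. The per-band
calibration is verified by simulation; counts of flagged bands should be
read with that over-dispersion in mind.

## The synthetic-data generator

`synth_spec()`/`gen_dataset()` generate the three input tables with the
statistical structure the analysis assumes, so the whole pipeline is
exercisable and testable without downloads. Defaults describe the study
conditions: 380 taxa × 36 characters (18 binary, 8 unordered, 6 ordered, 4
continuous) with 13.4% missing and 2.2% polymorphic cells; four factors
with the standard vocabularies (five growth forms, three habitats, five
Köppen-style climate types, six regions) at 3.6% missing and 16.5%
multi-valued cells; a two-block ecological structure (block 1: tropical
forest trees of Africa/South America; block 2: temperate-to-polar herbs
and shrubs of open or wet habitats in North America/Eurasia) mixed with a
uniform background at `association_strength = 0.8`; and species
latitudinal ranges (20° wide, ~20 records each) centred in the latitude
band of the species' climate category, which yields both a richness and a
disparity gradient by construction.

Trait states follow a **hierarchical Dirichlet model**. Each character has
a shared baseline state distribution `p0 ~ Dirichlet(0.8)`; each category
of the grouping factor draws its own distribution around it,
`p_g ~ Dirichlet(θ_g · S · p0)` with `S` the number of states. The
per-category `dispersion` θ controls within-category state entropy: the
expected within-category mismatch is `θS(1 − Σp0²)/(θS + 1)`, monotone in
θ, collapsing to a single state as θ → 0 and approaching the baseline
entropy ceiling for large θ. Crucially, because all categories share the
same baseline, between-category distances are bounded by that same ceiling
instead of dominating the within-category signal — a property a flat
(non-hierarchical) Dirichlet scheme lacks, and without which the planted
"tropical species are most disparate" condition is drowned by
between-group pairs leaking into rare categories through multi-membership.
For the same reason, the extra category of a multi-valued factor cell is
drawn from the taxon's own category distribution rather than uniformly, so
co-memberships are ecologically coherent (temperate + cold, not tropical +
polar). Continuous characters use a shared character mean, category means
jittered around it (SD 0.3), and category SD `cont_sd_scale · √θ_g`.

The default dispersions (tropical 3; arid and temperate 0.4; cold 0.3;
polar 0.15) plant a tropical disparity excess of roughly 0.05–0.10 on the
`D̄` scale — the same order as the contrasts floral datasets of this size
show — large enough to be unambiguous at n = 380 under 16.5% factor
polymorphism. `group_effect = FALSE` switches the planted trait structure
off entirely (one shared distribution for all taxa, at the mean
dispersion): that is the exchangeable null used to calibrate the
permutation ANOVA's type-I error, and the latitude-independent condition
for the richness-controlled-null check.

What the generator does **not** emulate: phylogenetic correlation among
taxa (the analyses make no phylogenetic correction either), spatial
structure in longitude, clumped rather than uniform missingness, and
correlated missingness between the trait and factor tables. Tests passing
on synthetic data therefore validate the statistical machinery and the
recovery of planted effects — not the biological claims one might make
from real matrices, which inherit all of those ignored dependencies.

## Scales, seeds and degenerate inputs

The drivers under `analysis/` run a desk-scale configuration: 999
permutations per test, 10 factor resolutions, 9999 permutations for the
cluster contrast, 1000 draws per band for the richness-controlled null.
Publication-scale values (9999 permutations, 100 resolutions, 99999
contrast permutations) are one argument away in `run_config()`; the
statistics are identical in expectation, only Monte-Carlo noise shrinks.
Every stochastic step takes an explicit seed, and `run_pipeline()` derives
all stage seeds from one master seed, so reruns with the same
configuration are byte-identical (checked in the tests).

Degenerate inputs are handled explicitly rather than silently: pairs with
no shared characters are undefined and excluded with a warning; groups
below two taxa make disparity undefined and tests impossible (error);
categories below three taxa are dropped from tests; zero-variance
responses make the Pearson correlation undefined (flagged NA); all-zero
shifted residual profiles are at distance 0; a zero contingency marginal
is an error that names the categories to merge or exclude.

## Known limitations

* The mean character difference treats all characters equally; no
  weighting, and no partial-distance correction for heavily missing
  characters beyond pairwise deletion.
* Random resolution of polymorphism treats states as equiprobable;
  frequency-weighted resolution would need data the matrix does not carry.
* The association network's Bray–Curtis-on-shifted-residuals construction
  is one of several defensible choices; it is isolated in
  `pr_profile_distance()` so an alternative can be swapped in without
  touching the tests of the chi-squared layer.
* Record-based presence understates ranges of poorly sampled species; the
  `range_fill` alternative overstates them. Both are available.
* Bands share species, so per-band null verdicts are correlated (see
  above); a field-wide joint test is not implemented.
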