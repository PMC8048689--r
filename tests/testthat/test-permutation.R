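# Distance-based permutation ANOVA and central-tendency post hoc tests.

euclid_dm <- function(X, taxa = paste0("t", seq_len(nrow(X)))) {
  as_dist_matrix(as.matrix(dist(X)), taxa)
}

test_that("F-ratio matches vegan::adonis2 on random euclidean data", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(36), 12)
    dm <- euclid_dm(X)
    g <- setNames(sample(rep(c("a", "b", "c"), 4)), dm$taxa)
    ref <- vegan::adonis2(dist(X) ~ grp, data = data.frame(grp = g),
                          permutations = 2)
    expect_equal(f_ratio(dm, g), ref$F[1], tolerance = 1e-10)
  }
})

test_that("F-ratio reduces to the classical one-way ANOVA F in the
           univariate euclidean limit", {
  set.seed(8)
  y <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  dm <- euclid_dm(matrix(y, ncol = 1))
  f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(f_ratio(dm, setNames(g, dm$taxa)), f_classic,
               tolerance = 1e-10)
})

test_that("degenerate partitions: equidistant taxa give F = 1 exactly,
           perfect separation gives an infinite F and the smallest
           attainable p", {
  # all pairwise distances equal: every grouping yields F = 1 exactly
  # (SS_total = (N - 1) c^2 / 2 + c^2 ... collapses so that the among- and
  # within-group mean squares coincide; cross-checked against adonis2)
  d <- matrix(0.5, 6, 6); diag(d) <- 0
  dm <- as_dist_matrix(d)
  g <- setNames(rep(c("a", "b"), each = 3), dm$taxa)
  expect_equal(f_ratio(dm, g), 1, tolerance = 1e-12)
  d9 <- matrix(0.3, 9, 9); diag(d9) <- 0
  dm9 <- as_dist_matrix(d9)
  g9 <- setNames(rep(c("a", "b", "c"), times = c(2, 3, 4)), dm9$taxa)
  expect_equal(f_ratio(dm9, g9), 1, tolerance = 1e-12)
  # ... and since every permuted F ties with the observed one, p = 1
  expect_equal(permutation_anova(dm, g, n_perm = 199, seed = 1)$p, 1)
  # perfect separation, large enough that no random permutation recreates
  # the partition: F = Inf and the smallest attainable p under each
  # convention
  d2 <- rbind(cbind(matrix(0, 10, 10), matrix(1, 10, 10)),
              cbind(matrix(1, 10, 10), matrix(0, 10, 10)))
  dm2 <- as_dist_matrix(d2)
  g2 <- setNames(rep(c("a", "b"), each = 10), dm2$taxa)
  expect_equal(f_ratio(dm2, g2), Inf)
  res <- permutation_anova(dm2, g2, n_perm = 499, seed = 1)
  expect_equal(res$p, 0)
  res1 <- permutation_anova(dm2, g2, n_perm = 499, seed = 1,
                            p_convention = "plus-one")
  expect_equal(res1$p, 1 / 500)
  # in a tiny instance the group-preserving permutations tie with the
  # observed infinite F and count toward p (ties-inclusive convention):
  # 2 of the 20 distinct 3|3 assignments recreate the separation
  d6 <- rbind(cbind(matrix(0, 3, 3), matrix(1, 3, 3)),
              cbind(matrix(1, 3, 3), matrix(0, 3, 3)))
  dm6 <- as_dist_matrix(d6)
  g6 <- setNames(rep(c("a", "b"), each = 3), dm6$taxa)
  p6 <- permutation_anova(dm6, g6, n_perm = 1999, seed = 2)$p
  expect_gt(p6, 0.05); expect_lt(p6, 0.17)
})

test_that("group size guards: fewer than 2 per group or 2 groups error", {
  dm <- as_dist_matrix(as.matrix(dist(1:5)))
  expect_error(f_ratio(dm, setNames(c("a", "a", "a", "b", "b"), dm$taxa)), NA)
  expect_error(f_ratio(dm, setNames(c("a", "a", "b", "b", "c"), dm$taxa)),
               "fewer than 2")
  expect_error(f_ratio(dm, setNames(rep("a", 5), dm$taxa)), "at least 2 groups")
  expect_error(permutation_anova(dm, setNames(rep(c("a", "b"), c(3, 2)),
                                              dm$taxa), n_perm = 0), "n_perm")
})

test_that("sampled permutation p matches exhaustive enumeration (<= 8 taxa)", {
  set.seed(123)
  for (rep in 1:3) {
    X <- matrix(rnorm(14), 7)
    dm <- euclid_dm(X)
    g <- setNames(rep(c("a", "b"), c(3, 4)), dm$taxa)
    p_exact <- oracle_anova_p(dm$d, 3)
    p_samp <- permutation_anova(dm, g, n_perm = 9999, seed = rep)$p
    expect_lt(abs(p_samp - p_exact), 0.02)
    # central tendency, 3 vs 3 on the first 6 taxa
    dm6 <- as_dist_matrix(dm$d[1:6, 1:6])
    g6 <- setNames(rep(c("a", "b"), each = 3), dm6$taxa)
    t_exact <- oracle_ct_p(dm6$d, 3)
    ph <- posthoc_pairwise(dm6, g6, n_perm = 9999, seed = rep)
    expect_lt(abs(ph$p_raw - t_exact), 0.02)
  }
})

test_that("p-values are invariant to relabelling categories and the
           permutation scheme preserves distances", {
  set.seed(4)
  X <- matrix(rnorm(24), 12)
  dm <- euclid_dm(X)
  g1 <- setNames(rep(c("a", "b"), 6), dm$taxa)
  g2 <- setNames(ifelse(g1 == "a", "zz", "qq"), dm$taxa)
  r1 <- permutation_anova(dm, g1, n_perm = 299, seed = 5)
  r2 <- permutation_anova(dm, g2, n_perm = 299, seed = 5)
  expect_equal(r1$f_obs, r2$f_obs)
  expect_equal(r1$p, r2$p)
})

test_that("post hoc tests: T of identical groups is 0 and Bonferroni is
           min(1, n_comparisons * p_raw)", {
  # two groups with identical internal distance structure
  block <- matrix(0.4, 4, 4); diag(block) <- 0
  d <- rbind(cbind(block, matrix(0.4, 4, 4)),
             cbind(matrix(0.4, 4, 4), block))
  dm <- as_dist_matrix(d)
  g <- setNames(rep(c("a", "b"), each = 4), dm$taxa)
  ph <- posthoc_pairwise(dm, g, n_perm = 99, seed = 1)
  expect_equal(ph$t_obs, 0)
  # three groups: 3 comparisons
  set.seed(2)
  X <- matrix(rnorm(18), 9)
  dm3 <- euclid_dm(X)
  g3 <- setNames(rep(c("a", "b", "c"), each = 3), dm3$taxa)
  ph3 <- posthoc_pairwise(dm3, g3, n_perm = 199, seed = 3)
  expect_equal(nrow(ph3), 3L)
  expect_equal(ph3$p_adj, pmin(1, 3 * ph3$p_raw))
  expect_true(all(ph3$p_adj >= ph3$p_raw))
  expect_true(all(abs(ph3$t_obs) <= 1))
})

test_that("factor resolution samples multi-valued cells uniformly and
           drops missing taxa", {
  ft <- make_ft(climate = c("temperate/cold", "tropical", "?"))
  picks <- vapply(1:400, function(s)
    resolve_factor_polymorphism(ft, "climate", seed = s)[["t1"]],
    character(1))
  expect_gt(mean(picks == "temperate"), 0.42)
  expect_lt(mean(picks == "temperate"), 0.58)
  asg <- resolve_factor_polymorphism(ft, "climate", seed = 1)
  expect_named(asg, c("t1", "t2"))
  # single-valued table is unchanged
  ft2 <- make_ft(climate = c("tropical", "arid"))
  expect_equal(resolve_factor_polymorphism(ft2, "climate", seed = 9),
               c(t1 = "tropical", t2 = "arid"))
})

test_that("aggregation over resolutions: polymorphism-free input has zero
           spread, tiny categories are dropped", {
  spec <- synth_spec(n_taxa = 30, char_plan = c(binary = 6, unordered = 2,
                                                ordered = 1, continuous = 1),
                     missing_frac = 0.05, morph_polym_frac = 0,
                     factor_polym_frac = 0, factor_missing_frac = 0,
                     seed = 77)
  ds <- gen_dataset(spec)
  agg <- suppressWarnings(
    aggregate_over_resolutions(ds$m, ds$ft, "climate", "anova",
                               n_perm = 199, n_resolutions = 5,
                               base_seed = 3))
  expect_equal(agg$stat_sd, 0)
  expect_equal(agg$p_sd, 0)
  expect_equal(agg$n_resolutions, 1L)
  # with polymorphism the statistic genuinely varies across resolutions
  spec2 <- synth_spec(n_taxa = 40, char_plan = c(binary = 6, unordered = 2,
                                                 ordered = 1, continuous = 1),
                      missing_frac = 0.05, morph_polym_frac = 0.1,
                      factor_polym_frac = 0.3, factor_missing_frac = 0,
                      seed = 78)
  ds2 <- gen_dataset(spec2)
  agg2 <- suppressWarnings(
    aggregate_over_resolutions(ds2$m, ds2$ft, "climate", "anova",
                               n_perm = 199, n_resolutions = 6,
                               base_seed = 4))
  expect_equal(agg2$n_resolutions, 6L)
  expect_gt(agg2$stat_sd, 0)
  # small-category rule
  g <- setNames(c(rep("a", 5), rep("b", 2)), paste0("t", 1:7))
  expect_warning(gf <- floradisp:::filter_small_groups(g, 3),
                 "fewer than 3")
  expect_setequal(unique(gf), "a")
})

test_that("mean F grows with the planted between-group effect", {
  f_at <- function(strength, seed) {
    spec <- synth_spec(n_taxa = 36, char_plan = c(binary = 8, unordered = 2,
                                                  ordered = 0, continuous = 0),
                       missing_frac = 0, morph_polym_frac = 0,
                       factor_polym_frac = 0, factor_missing_frac = 0,
                       association_strength = 0,
                       group_effect = strength > 0,
                       dispersion = c(tropical = 0.4, arid = 0.4,
                                      temperate = 0.4, cold = 0.4,
                                      polar = 0.4),
                       seed = seed)
    ds <- gen_dataset(spec)
    dm <- distance_matrix(ds$m)
    g <- floradisp:::filter_small_groups(
      resolve_factor_polymorphism(ds$ft, "climate"), quiet = TRUE)
    f_ratio(dm, g)
  }
  f_null <- mean(vapply(1:8, function(s) f_at(0, s), numeric(1)))
  f_eff <- mean(vapply(1:8, function(s) f_at(1, s + 50), numeric(1)))
  expect_gt(f_eff, f_null)
})
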