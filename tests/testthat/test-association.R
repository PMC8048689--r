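# Chi-squared association tests, Pearson-residual networks and NMDS.

test_that("contingency counting follows the Cartesian-product rule", {
  ft <- make_ft(climate = c("temperate", "tropical", "temperate/cold", "cold"),
                region = c("Eurasia/Africa", "Africa", "Eurasia", "?"))
  ct <- build_contingency(ft, "climate", "region")
  # t1: temperate x {Eurasia, Africa}; t2: tropical x Africa;
  # t3: {temperate, cold} x Eurasia; t4 excluded (missing region)
  expect_equal(ct$counts["temperate", "Eurasia"], 2L)
  expect_equal(ct$counts["temperate", "Africa"], 1L)
  expect_equal(ct$counts["tropical", "Africa"], 1L)
  expect_equal(ct$counts["cold", "Eurasia"], 1L)
  expect_equal(sum(ct$counts), 5L)
  expect_equal(ct$n_taxa, 3L)
})

test_that("merges pool counts and exclusions drop categories", {
  ft <- make_ft(climate = c("polar", "cold", "cold", "tropical", "tropical",
                            "polar/cold"),
                habitat = c("open", "open", "forests", "forests", "forests",
                            "open"))
  ct <- build_contingency(ft, "climate", "habitat",
                          merges = c(polar = "cold"))
  expect_false("polar" %in% rownames(ct$counts))
  # polar counts landed in cold; the polar/cold cell collapses to one count
  expect_equal(ct$counts["cold", "open"], 3L)
  ct2 <- build_contingency(ft, "climate", "habitat",
                           merges = c(polar = "cold"),
                           exclusions = "tropical")
  expect_false("tropical" %in% rownames(ct2$counts))
  # a category with zero marginal is a hard error suggesting merges
  ft3 <- make_ft(climate = c("cold", "cold", "tropical", "tropical"),
                 habitat = c("open", "open", "forests", "forests"))
  ft3$factors$climate <- c("cold", "tropical", "polar")
  expect_error(build_contingency(ft3, "climate", "habitat"), "polar")
  expect_error(build_contingency(ft, "climate", "climate"), "distinct")
})

test_that("chi-squared closed forms: perfect association and independence", {
  res <- chi_squared(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(res$chi2, 20, tolerance = 1e-12)
  expect_equal(res$df, 1)
  # independence: counts equal to the outer product of the marginals
  ind <- outer(c(20, 40), c(30, 30)) / 60
  res2 <- chi_squared(ind)
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  expect_true(all(abs(res2$pr) < 1e-8))
  # Pearson residual of a single cell: (10 - 5) / sqrt(5)
  expect_equal((10 - 5) / sqrt(5), 2.2361, tolerance = 1e-4)
  # df arithmetic and residual identities on a random table
  set.seed(1)
  tab <- matrix(rpois(12, 20) + 1, 3, 4)
  r3 <- chi_squared(tab)
  expect_equal(r3$df, (3 - 1) * (4 - 1))
  expect_equal(sum(tab - r3$expected), 0, tolerance = 1e-9)
  expect_equal(r3$pr, (tab - r3$expected) / sqrt(r3$expected),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("edge extraction: significance gate, PR threshold and sign", {
  pr <- matrix(c(3.1, -3.1, -0.5, 0.5), 2, 2,
               dimnames = list(c("a1", "a2"), c("b1", "b2")))
  sig <- structure(list(chi2 = 15, df = 1, p = 1e-4, pr = pr,
                        factor_a = "A", factor_b = "B"),
                   class = "association_result")
  nosig <- sig; nosig$p <- 0.4
  edges <- association_edges(list(sig), alpha = 0.05, pr_threshold = 2)
  expect_equal(nrow(edges), 2L)
  neg <- edges[edges$cat_a == "a2", ]
  expect_equal(neg$sign, -1)
  expect_equal(neg$weight, 3.1)
  expect_equal(nrow(association_edges(list(nosig))), 0L)       # not significant
  expect_equal(nrow(association_edges(list(sig), pr_threshold = 10)), 0L)
})

test_that("PR profile distances follow Bray-Curtis after the global shift", {
  # two factors with two categories each: profiles are single PR values
  pr <- matrix(c(1, -1, -1, 1), 2, 2,
               dimnames = list(c("a1", "a2"), c("b1", "b2")))
  res <- list(structure(list(chi2 = 1, df = 1, p = 0.01, pr = pr,
                             factor_a = "A", factor_b = "B"),
                        class = "association_result"))
  D <- pr_profile_distance(res)
  # after shifting by the global min (-1), a1's profile against B is (2, 0)
  # and a2's is (0, 2): Bray-Curtis (|2-0| + |0-2|) / (2 + 2) = 1
  expect_equal(D["a1", "a2"], 1)
  expect_equal(D["b1", "b2"], 1)
  # identical profiles at distance 0, symmetry, zero diagonal
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
})

test_that("NMDS embedding: determinism, exact 2-D recovery, equilateral
           configuration", {
  # three mutually equidistant categories embed as an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  emb <- suppressWarnings(nmds_embed(d3, seed = 1, n_starts = 5))
  side <- dist(emb$coordinates)
  expect_lt(max(side) - min(side), 0.05 * mean(side))
  expect_lt(emb$stress, 0.01)
  # distances realisable in 2-D are recovered with near-zero stress
  set.seed(3)
  pts <- matrix(rnorm(16), 8)
  d8 <- as.matrix(dist(pts))
  dimnames(d8) <- list(paste0("c", 1:8), paste0("c", 1:8))
  emb8 <- suppressWarnings(nmds_embed(d8, seed = 2, n_starts = 20))
  expect_lt(emb8$stress, 0.01)
  emb8b <- suppressWarnings(nmds_embed(d8, seed = 2, n_starts = 20))
  expect_identical(emb8$coordinates, emb8b$coordinates)
  # coordinates are centred with unit RMS point norm
  expect_equal(colMeans(emb8$coordinates), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-9)
  expect_equal(mean(rowSums(emb8$coordinates^2)), 1, tolerance = 1e-9)
})

test_that("edge list is invariant under factor order swap", {
  ft <- gen_factor_table(synth_spec(n_taxa = 150, association_strength = 0.9,
                                    factor_missing_frac = 0,
                                    factor_polym_frac = 0, seed = 5))
  r_ab <- chi_squared(build_contingency(ft, "climate", "habitat"))
  r_ba <- chi_squared(build_contingency(ft, "habitat", "climate"))
  expect_equal(r_ab$chi2, r_ba$chi2, tolerance = 1e-9)
  e_ab <- association_edges(list(r_ab))
  e_ba <- association_edges(list(r_ba))
  key <- function(e) sort(paste(pmin(e$cat_a, e$cat_b),
                                pmax(e$cat_a, e$cat_b), round(e$pr, 6)))
  expect_equal(key(e_ab), key(e_ba))
})

test_that("planted two-block structure is recovered: PR signs and a 2-means
           split of the NMDS plane", {
  block1 <- c("tropical", "trees", "forests", "Africa", "South America")
  block2 <- c("temperate", "cold", "herbs and aquatic herbs", "shrubs",
              "open", "wet", "North America", "Eurasia")
  ok_signs <- 0L; ok_split <- 0L; n_rep <- 25L
  for (r in seq_len(n_rep)) {
    ft <- gen_factor_table(synth_spec(n_taxa = 300,
                                      association_strength = 0.85,
                                      factor_missing_frac = 0,
                                      factor_polym_frac = 0.1,
                                      seed = 1000 + r))
    scan <- association_scan(ft, merges = c(polar = "cold"),
                             exclusions = "root parasites")
    # sign pattern: within-block PR positive for the core category pairs
    core <- list(c("tropical", "trees"), c("tropical", "forests"),
                 c("temperate", "open"), c("trees", "forests"))
    signs_ok <- all(vapply(core, function(pp) {
      for (res in scan) {
        pr <- res$pr
        if (pp[1] %in% rownames(pr) && pp[2] %in% colnames(pr))
          return(pr[pp[1], pp[2]] > 0)
        if (pp[2] %in% rownames(pr) && pp[1] %in% colnames(pr))
          return(pr[pp[2], pp[1]] > 0)
      }
      NA
    }, logical(1)))
    if (isTRUE(signs_ok)) ok_signs <- ok_signs + 1L
    D <- pr_profile_distance(scan)
    emb <- suppressWarnings(nmds_embed(D, seed = r, n_starts = 10))
    km <- kmeans(emb$coordinates, centers = 2, nstart = 10)
    cl <- km$cluster
    b1 <- intersect(block1, names(cl)); b2 <- intersect(block2, names(cl))
    split_ok <- length(unique(cl[b1])) == 1L &&
      length(unique(cl[b2])) == 1L && cl[b1][1] != cl[b2][1]
    if (isTRUE(split_ok)) ok_split <- ok_split + 1L
  }
  expect_gte(ok_signs / n_rep, 0.95)
  expect_gte(ok_split / n_rep, 0.9)
})

test_that("network clusters are the connected components of positive edges", {
  edges <- data.frame(
    cat_a = c("tropical", "trees", "temperate", "tropical"),
    cat_b = c("trees", "forests", "open", "open"),
    factor_a = "x", factor_b = "y",
    sign = c(1, 1, 1, -1), weight = c(3, 2.5, 2.2, 4),
    pr = c(3, 2.5, 2.2, -4), stringsAsFactors = FALSE)
  cl <- network_clusters(edges)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]], c("tropical", "trees", "forests"))
  expect_setequal(cl[[2]], c("temperate", "open"))
})
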