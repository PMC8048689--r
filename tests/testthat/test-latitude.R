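# Latitudinal binning, gradient statistics and the richness-controlled null.

occ_df <- function(...) occurrence_table(data.frame(...))

test_that("binning follows the half-open 10-degree convention", {
  occ <- occ_df(species = c("sp1", "sp2", "sp2", "sp3"),
                latitude = c(5.3, -12.0, 23.0, 10.0),
                longitude = 0)
  prof <- bin_presence(occ)
  expect_equal(nrow(prof$bins), 18L)
  expect_equal(prof$bins$lower, seq(-90, 80, 10))
  bin_of <- function(lo) which(prof$bins$lower == lo)
  expect_setequal(prof$present[[bin_of(0)]], "sp1")
  # record-based presence: no interpolation between -12 and 23
  expect_setequal(prof$present[[bin_of(-20)]], "sp2")
  expect_setequal(prof$present[[bin_of(20)]], "sp2")
  expect_equal(prof$bins$richness[bin_of(10)], 1L)  # 10.0 lands in [10, 20)
  expect_setequal(prof$present[[bin_of(10)]], "sp3")
  expect_equal(sum(prof$bins$richness), 4L)
  # bins partition [-90, 90): every record lands in exactly one bin
  expect_equal(sum(lengths(prof$present)), 4L)
})

test_that("range_fill marks the bins between a species' extreme records", {
  occ <- occ_df(species = "sp2", latitude = c(-12, 23), longitude = 0)
  prof <- bin_presence(occ, range_fill = TRUE)
  filled <- which(vapply(prof$present, function(s) "sp2" %in% s, logical(1)))
  expect_equal(prof$bins$lower[filled], seq(-20, 20, 10))
})

test_that("per-bin disparity is group disparity of the present species", {
  m <- random_fixture(6, seed = 17, missing_frac = 0)
  dm <- distance_matrix(m)
  occ <- occ_df(species = c("t1", "t2", "t3", "t4"),
                latitude = c(5, 5, 15, 75), longitude = 0)
  prof <- profile_disparity(bin_presence(occ), dm)
  b0 <- which(prof$bins$lower == 0)
  expect_equal(prof$bins$disparity[b0], dm$d["t1", "t2"])
  # singleton and empty bins are undefined
  expect_true(is.na(prof$bins$disparity[prof$bins$lower == 70]))
  expect_true(is.na(prof$bins$disparity[prof$bins$lower == -50]))
})

test_that("gradient statistics match closed-form least squares on a
           5-bin fixture", {
  # hand-made profile: responses at |mid| = 5, 15, 25, 35, 45
  prof <- list(bins = data.frame(
    bin = 1:5, lower = seq(0, 40, 10), upper = seq(10, 50, 10),
    mid = seq(5, 45, 10), richness = c(40L, 30L, 25L, 12L, 3L)))
  class(prof) <- "lat_profile"
  gs <- gradient_stats(prof, "richness")
  x <- seq(5, 45, 10); y <- c(40, 30, 25, 12, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  t_stat <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(gs$r, r_hand, tolerance = 1e-12)
  expect_equal(gs$slope, slope_hand, tolerance = 1e-12)
  expect_equal(gs$intercept, mean(y) - slope_hand * mean(x), tolerance = 1e-12)
  expect_equal(gs$p, 2 * pt(abs(t_stat), df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # exactly linear response: r = -1
  prof2 <- prof; prof2$bins$richness <- as.integer(100 - 2 * prof$bins$mid)
  expect_equal(gradient_stats(prof2, "richness")$r, -1, tolerance = 1e-12)
  # constant response: flagged undefined
  prof3 <- prof; prof3$bins$richness <- rep(7L, 5)
  expect_warning(gs3 <- gradient_stats(prof3, "richness"), "zero variance")
  expect_true(is.na(gs3$r))
  # the min-richness filter drops species-poor bins
  gs4 <- gradient_stats(prof, "richness", min_richness = 5)
  expect_equal(gs4$n_bins, 4L)
})

test_that("regression on synthetic linear-gradient data recovers the slope", {
  set.seed(5)
  true_slope <- -1.2; true_int <- 90
  mids <- seq(5, 85, 10)
  rich <- pmax(1, round(true_int + true_slope * mids + rnorm(9, 0, 3)))
  prof <- list(bins = data.frame(bin = 1:9, lower = seq(0, 80, 10),
                                 upper = seq(10, 90, 10), mid = mids,
                                 richness = as.integer(rich)))
  class(prof) <- "lat_profile"
  gs <- gradient_stats(prof, "richness")
  fit <- summary(lm(rich ~ mids))
  expect_lt(abs(gs$slope - true_slope), 2 * fit$coefficients[2, 2])
})

test_that("richness-controlled null: clone bins fall below the envelope,
           random bins inside, envelope shrinks with richness", {
  # pool: 5 identical taxa (clones) + 20 heterogeneous taxa
  set.seed(6)
  n <- 25
  d <- matrix(runif(n * n, 0.3, 0.8), n); d <- (d + t(d)) / 2; diag(d) <- 0
  d[1:5, 1:5] <- 0
  dm <- as_dist_matrix(d)
  occ <- occ_df(
    species = c(paste0("t", 1:5),                 # clones near the equator
                sample(dm$taxa, 8)),              # random set at 30-40
    latitude = c(rep(5, 5), rep(35, 8)), longitude = 0)
  prof <- profile_disparity(bin_presence(occ), dm)
  nulltab <- richness_controlled_null(prof, dm, n_draws = 400, seed = 8)
  clone_bin <- which(prof$bins$lower == 0)
  rand_bin <- which(prof$bins$lower == 30)
  expect_lt(nulltab$observed[clone_bin], nulltab$q025[clone_bin])
  expect_lt(nulltab$p_emp[clone_bin], 0.05)
  expect_gt(nulltab$observed[rand_bin], nulltab$q025[rand_bin])
  expect_lt(nulltab$observed[rand_bin], nulltab$q975[rand_bin])
  # envelope width decreases as bin richness grows
  width_at <- function(nb) {
    occ2 <- occ_df(species = dm$taxa[1:nb], latitude = rep(5, nb),
                   longitude = 0)
    p2 <- profile_disparity(bin_presence(occ2), dm)
    nt <- richness_controlled_null(p2, dm, n_draws = 400, seed = 9)
    b <- which(p2$bins$lower == 0)
    nt$q975[b] - nt$q025[b]
  }
  expect_gt(width_at(4), width_at(16))
})

test_that("null calibration: a uniformly drawn bin is inside the 95%
           envelope about 95% of the time", {
  set.seed(12)
  m <- random_fixture(18, seed = 55, missing_frac = 0)
  dm <- distance_matrix(m)
  inside <- 0L; n_rep <- 80L
  for (r in seq_len(n_rep)) {
    sp <- sample(dm$taxa, 6)
    occ <- occ_df(species = sp, latitude = rep(5, 6), longitude = 0)
    prof <- profile_disparity(bin_presence(occ), dm)
    nt <- richness_controlled_null(prof, dm, n_draws = 300, seed = 100 + r)
    b <- which(prof$bins$lower == 0)
    if (nt$observed[b] >= nt$q025[b] && nt$observed[b] <= nt$q975[b])
      inside <- inside + 1L
  }
  expect_gte(inside / n_rep, 0.85)
})
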