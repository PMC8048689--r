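#' Randomly resolve multi-membership for one factor
#'
#' Group-based tests need every taxon in exactly one category, so a
#' polymorphism-free factor assignment is sampled before each test: every
#' multi-valued cell is replaced by one of its categories drawn uniformly.
#' Taxa with a missing value for the factor are excluded from the
#' assignment (and hence from the tests).
#'
#' @param ft a [factor_table()].
#' @param factor factor name.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return named character vector: `names` are taxa, values the resolved
#'   category.
#' @export
resolve_factor_polymorphism <- function(ft, factor, seed = NULL) {
  if (!factor %in% names(ft$factors)) stop("unknown factor: ", factor)
  set_seed_if(seed)
  fk <- match(factor, names(ft$factors))
  cells <- ft$cells[, fk]
  keep <- lengths(cells) > 0L
  out <- vapply(cells[keep], function(st)
    if (length(st) == 1L) st else st[sample.int(length(st), 1L)],
    character(1))
  names(out) <- ft$taxa[keep]
  out
}

## drop categories below a minimal size (tiny categories such as the
## two-species root parasites are uninformative in permutation tests)
filter_small_groups <- function(groups, min_size = 3L, quiet = FALSE) {
  tab <- table(groups)
  small <- names(tab)[tab < min_size]
  if (length(small)) {
    if (!quiet)
      warning("dropping categories with fewer than ", min_size, " taxa: ",
              paste(small, collapse = ", "))
    groups <- groups[!(groups %in% small)]
  }
  groups
}

## distance submatrix (and its square) for the taxa of an assignment
dist_for_groups <- function(dm, groups) {
  taxa <- names(groups)
  if (is.null(taxa)) stop("groups must be a named vector (names = taxa)")
  taxa <- intersect(taxa, dm$taxa)
  groups <- groups[taxa]
  idx <- match(taxa, dm$taxa)
  d <- dm$d[idx, idx, drop = FALSE]
  if (anyNA(d))
    stop("undefined pairwise distances among grouped taxa; ",
         "permutation tests need a complete distance matrix")
  list(d = d, groups = as.character(groups), taxa = taxa)
}

## F-ratio from a squared-distance matrix A (zero diagonal) and integer
## group codes; pos = list of index vectors per group
f_from_A <- function(A, pos, N, a) {
  ss_tot <- sum(A) / (2 * N)
  ss_w <- 0
  for (g in pos) ss_w <- ss_w + sum(A[g, g]) / (2 * length(g))
  ss_among <- ss_tot - ss_w
  if (ss_w <= 0) return(Inf)
  (ss_among / (a - 1)) / (ss_w / (N - a))
}

#' Distance-based one-way F-ratio
#'
#' Pseudo-F for a one-way partition of a distance matrix, from the standard
#' decomposition of squared interpoint distances:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `SS_among = SS_total - SS_within`, and
#' `F = (SS_among / (a - 1)) / (SS_within / (N - a))`. For Euclidean
#' distances on a single variable this reduces to the classical one-way
#' ANOVA F. Perfect separation (`SS_within = 0`) returns `Inf`.
#'
#' @param dm a `dist_matrix`.
#' @param groups named character vector mapping taxa to categories; every
#'   category must have at least 2 taxa.
#' @return the F-ratio (numeric scalar, `>= 0`, possibly `Inf`).
#' @export
f_ratio <- function(dm, groups) {
  gd <- dist_for_groups(dm, groups)
  tab <- table(gd$groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("groups with fewer than 2 taxa: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  A <- gd$d^2
  pos <- split(seq_along(gd$groups), gd$groups)
  f_from_A(A, pos, length(gd$groups), length(pos))
}

perm_pvalue <- function(count, n_perm, convention) {
  switch(convention,
         count = count / n_perm,
         `plus-one` = (count + 1) / (n_perm + 1))
}

#' Permutation ANOVA on a distance matrix
#'
#' Compares the observed [f_ratio()] with its distribution under random
#' reassignment of taxa to groups (equivalently: assigning a random row of
#' the morphological matrix to each species without replacement, which
#' permutes taxon identities of the distance matrix while preserving the
#' multiset of distances). The p-value is the fraction of permuted F-ratios
#' greater than or equal to the observed one; with the default `"count"`
#' convention a never-exceeded statistic reports exactly 0, the
#' `"plus-one"` convention reports `(count + 1) / (n_perm + 1)`.
#'
#' @inheritParams f_ratio
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param p_convention `"count"` (default) or `"plus-one"`.
#' @return object of class `permutation_anova_result`: list with `f_obs`,
#'   `p`, `n_perm`, `group_sizes`, `p_convention`.
#' @export
permutation_anova <- function(dm, groups, n_perm = 9999, seed = NULL,
                              p_convention = c("count", "plus-one")) {
  p_convention <- match.arg(p_convention)
  if (n_perm < 1) stop("n_perm must be >= 1")
  gd <- dist_for_groups(dm, groups)
  tab <- table(gd$groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("groups with fewer than 2 taxa: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  A <- gd$d^2
  N <- length(gd$groups); a <- length(tab)
  pos <- split(seq_len(N), gd$groups)
  f_obs <- f_from_A(A, pos, N, a)
  set_seed_if(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    ppos <- lapply(pos, function(g) perm[g])
    if (f_from_A(A, ppos, N, a) >= f_obs) count <- count + 1L
  }
  structure(list(f_obs = f_obs, p = perm_pvalue(count, n_perm, p_convention),
                 n_perm = n_perm, group_sizes = as.list(tab),
                 p_convention = p_convention),
            class = "permutation_anova_result")
}

#' @export
print.permutation_anova_result <- function(x, ...) {
  cat(sprintf("permutation ANOVA: F = %.4g, P = %.4g (%d permutations)\n",
              x$f_obs, x$p, x$n_perm))
  cat("  group sizes:",
      paste(names(x$group_sizes), unlist(x$group_sizes), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

## mean within-group pairwise distance for index set idx (d has 0 diagonal)
within_mean <- function(d, idx) {
  n <- length(idx)
  sum(d[idx, idx]) / (n * (n - 1))
}

## two-group central-tendency permutation test on a distance submatrix;
## labels are shuffled over the union of the two groups, keeping sizes.
## d must be in a canonical (swap-invariant) row order and selA flag the
## rows of group A, so that swapping A and B only flips the sign of T and
## reuses the identical permutation stream (p is then exactly symmetric).
central_tendency_test <- function(d, selA, n_perm, seed, p_convention) {
  t_obs <- within_mean(d, which(selA)) - within_mean(d, which(!selA))
  set_seed_if(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    sp <- selA[sample.int(length(selA))]
    t_b <- within_mean(d, which(sp)) - within_mean(d, which(!sp))
    if (abs(t_b) >= abs(t_obs)) count <- count + 1L
  }
  list(t_obs = t_obs, p = perm_pvalue(count, n_perm, p_convention))
}

#' Pairwise central-tendency permutation tests
#'
#' Post-hoc companion of [permutation_anova()]: for every unordered pair of
#' categories, the statistic `T` is the difference between the two
#' categories' mean within-category pairwise distances; its null
#' distribution is obtained by shuffling the taxa of the two categories
#' (two-category subset only), and the two-sided p-value is the fraction of
#' permutations with `|T|` at least the observed `|T|`. Raw p-values are
#' Bonferroni-adjusted for the number of pairs tested.
#'
#' @inheritParams permutation_anova
#' @return object of class `pairwise_test_result`: data frame with columns
#'   `cat_a`, `cat_b`, `t_obs`, `p_raw`, `p_adj`.
#' @export
posthoc_pairwise <- function(dm, groups, n_perm = 9999, seed = NULL,
                             p_convention = c("count", "plus-one")) {
  p_convention <- match.arg(p_convention)
  gd <- dist_for_groups(dm, groups)
  tab <- table(gd$groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L))
    stop("groups with fewer than 2 taxa: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  levs <- names(tab)
  pairs <- utils::combn(levs, 2L)
  n_comp <- ncol(pairs)
  seeds <- if (is.null(seed)) rep(list(NULL), n_comp)
           else as.list(spawn_seeds(seed, n_comp))
  res <- vector("list", n_comp)
  for (j in seq_len(n_comp)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    idx <- which(gd$groups %in% c(a, b))
    d <- gd$d[idx, idx, drop = FALSE]
    ct <- central_tendency_test(d, gd$groups[idx] == a, n_perm, seeds[[j]],
                                p_convention)
    res[[j]] <- data.frame(cat_a = a, cat_b = b, t_obs = ct$t_obs,
                           p_raw = ct$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_raw * n_comp)
  class(out) <- c("pairwise_test_result", "data.frame")
  out
}

#' Aggregate a permutation test over random resolutions of polymorphism
#'
#' The grouping factor (and the morphological matrix itself) may contain
#' polymorphic cells; both are therefore randomly resolved before each
#' test, and the test repeated `n_resolutions` times with a fresh
#' resolution of the factor and a freshly recomputed distance matrix each
#' time. Statistics and p-values are reported as mean +/- SD over the
#' resolutions. When neither table contains relevant polymorphism the
#' repetitions would be identical, so a single run is performed and the SDs
#' are exactly 0.
#'
#' @param m a [morph_matrix()].
#' @param ft a [factor_table()].
#' @param factor grouping factor name.
#' @param test `"anova"` or `"posthoc"`.
#' @param n_perm permutations per test.
#' @param n_resolutions number of random polymorphism resolutions.
#' @param base_seed integer; deterministically spawns all per-resolution
#'   seeds.
#' @param min_group_size categories with fewer taxa than this (after
#'   resolution) are dropped from the test.
#' @param p_convention passed to the underlying test.
#' @return object of class `aggregated_result`. For `"anova"`: list with
#'   `stat_mean`, `stat_sd`, `p_mean`, `p_sd`, `n_resolutions` and a
#'   `per_resolution` data frame. For `"posthoc"`: same fields where
#'   `stat_*`/`p_*` are data frames with one row per category pair
#'   (columns `t_mean`, `t_sd`, `p_raw_mean`, `p_raw_sd`, `p_adj_mean`,
#'   `p_adj_sd`, `n_present`).
#' @export
aggregate_over_resolutions <- function(m, ft, factor,
                                       test = c("anova", "posthoc"),
                                       n_perm = 9999, n_resolutions = 100,
                                       base_seed = 1L, min_group_size = 3L,
                                       p_convention = c("count", "plus-one")) {
  test <- match.arg(test)
  p_convention <- match.arg(p_convention)
  if (n_resolutions < 1) stop("n_resolutions must be >= 1")
  fk <- match(factor, names(ft$factors))
  if (is.na(fk)) stop("unknown factor: ", factor)
  has_poly <- polymorphic_fraction(m) > 0 ||
    any(lengths(ft$cells[, fk]) > 1L)
  n_eff <- if (has_poly) n_resolutions else 1L
  seeds <- matrix(spawn_seeds(base_seed, 3L * n_resolutions),
                  ncol = 3L)  # morph / factor / permutation seeds
  runs <- vector("list", n_eff)
  for (r in seq_len(n_eff)) {
    dm <- distance_matrix(m, seed = seeds[r, 1])
    groups <- resolve_factor_polymorphism(ft, factor, seed = seeds[r, 2])
    groups <- filter_small_groups(groups, min_group_size, quiet = r > 1L)
    runs[[r]] <- tryCatch(
      if (test == "anova")
        permutation_anova(dm, groups, n_perm, seed = seeds[r, 3],
                          p_convention = p_convention)
      else
        posthoc_pairwise(dm, groups, n_perm, seed = seeds[r, 3],
                         p_convention = p_convention),
      error = function(e)
        stop("resolution ", r, ": ", conditionMessage(e), call. = FALSE))
  }
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  if (test == "anova") {
    f <- vapply(runs, `[[`, numeric(1), "f_obs")
    p <- vapply(runs, `[[`, numeric(1), "p")
    out <- list(test = "anova", factor = factor,
                stat_mean = mean(f), stat_sd = sd0(f),
                p_mean = mean(p), p_sd = sd0(p),
                n_resolutions = n_eff,
                per_resolution = data.frame(resolution = seq_len(n_eff),
                                            f_obs = f, p = p))
  } else {
    all_rows <- do.call(rbind, lapply(seq_along(runs), function(r)
      cbind(runs[[r]], resolution = r)))
    key <- paste(all_rows$cat_a, all_rows$cat_b, sep = " vs ")
    agg <- function(v) c(tapply(v, key, mean), recursive = TRUE)
    aggsd <- function(v) c(tapply(v, key, sd0), recursive = TRUE)
    pairs <- sort(unique(key))
    stats_df <- data.frame(
      pair = pairs,
      t_mean = agg(all_rows$t_obs)[pairs],
      t_sd = aggsd(all_rows$t_obs)[pairs],
      p_raw_mean = agg(all_rows$p_raw)[pairs],
      p_raw_sd = aggsd(all_rows$p_raw)[pairs],
      p_adj_mean = agg(all_rows$p_adj)[pairs],
      p_adj_sd = aggsd(all_rows$p_adj)[pairs],
      n_present = c(table(key)[pairs]),
      row.names = NULL, stringsAsFactors = FALSE)
    out <- list(test = "posthoc", factor = factor, pairs = stats_df,
                n_resolutions = n_eff, per_resolution = all_rows)
  }
  class(out) <- "aggregated_result"
  out
}

#' @export
print.aggregated_result <- function(x, ...) {
  cat("aggregated over", x$n_resolutions, "polymorphism resolution(s);",
      "factor:", x$factor, "\n")
  if (x$test == "anova") {
    cat(sprintf("  F = %.2f +/- %.2f, P = %.3g +/- %.3g\n",
                x$stat_mean, x$stat_sd, x$p_mean, x$p_sd))
  } else {
    print(x$pairs, digits = 4)
  }
  invisible(x)
}
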