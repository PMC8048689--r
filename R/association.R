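#' Contingency table between the categories of two factors
#'
#' Each taxon scored for both factors contributes one count to every
#' combination of its category sets (Cartesian-product counting), so a
#' species growing in both temperate and cold areas of Eurasia adds counts
#' to (temperate, Eurasia) and (cold, Eurasia). Category merges (e.g. the
#' small polar category pooled into cold) and exclusions (e.g. a two-species
#' category) are applied first so the expected counts meet the chi-squared
#' test assumptions.
#'
#' @param ft a [factor_table()].
#' @param factor_a,factor_b two distinct factor names.
#' @param merges named character vector: `c(old = "new")` relabels category
#'   `old` as `new` (in whichever factor it occurs).
#' @param exclusions character vector of categories removed before counting.
#' @return object of class `contingency_table`: list with `counts` (matrix,
#'   rows = categories of `factor_a`), `factor_a`, `factor_b`, `merges`,
#'   `exclusions`, `n_taxa` used.
#' @export
build_contingency <- function(ft, factor_a, factor_b,
                              merges = character(), exclusions = character()) {
  if (factor_a == factor_b) stop("factors must be distinct")
  for (f in c(factor_a, factor_b))
    if (!f %in% names(ft$factors)) stop("unknown factor: ", f)
  relabel <- function(st) {
    st <- st[!(st %in% exclusions)]
    hit <- st %in% names(merges)
    st[hit] <- unname(merges[st[hit]])
    unique(st)
  }
  vocab <- function(f) {
    v <- relabel(ft$factors[[f]])
    v[!duplicated(v)]
  }
  ra <- vocab(factor_a); rb <- vocab(factor_b)
  counts <- matrix(0L, length(ra), length(rb), dimnames = list(ra, rb))
  ka <- match(factor_a, names(ft$factors))
  kb <- match(factor_b, names(ft$factors))
  n_used <- 0L
  for (i in seq_along(ft$taxa)) {
    sa <- relabel(ft$cells[[i, ka]])
    sb <- relabel(ft$cells[[i, kb]])
    if (length(sa) == 0L || length(sb) == 0L) next
    n_used <- n_used + 1L
    for (a in sa) for (b in sb)
      counts[a, b] <- counts[a, b] + 1L
  }
  zero_r <- rownames(counts)[rowSums(counts) == 0]
  zero_c <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_r) || length(zero_c))
    stop("zero marginal for categories: ",
         paste(c(zero_r, zero_c), collapse = ", "),
         "; consider merging or excluding them")
  structure(list(counts = counts, factor_a = factor_a, factor_b = factor_b,
                 merges = merges, exclusions = exclusions, n_taxa = n_used),
            class = "contingency_table")
}

#' Pearson chi-squared test of association with residuals
#'
#' Plain Pearson chi-squared test (no continuity correction) of independence
#' between the two factors of a contingency table; expected counts from the
#' product of marginals. The cell-wise Pearson residuals
#' `(O - E) / sqrt(E)` carry the direction and strength of each pairwise
#' category association.
#'
#' @param ct a `contingency_table` (or a plain counts matrix).
#' @return object of class `association_result`: list with `chi2`, `df`,
#'   `p`, `pr` (Pearson residual matrix), `expected`, `factor_a`,
#'   `factor_b`.
#' @export
chi_squared <- function(ct) {
  counts <- if (inherits(ct, "contingency_table")) ct$counts else as.matrix(ct)
  if (any(counts < 0)) stop("negative counts")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ht$expected == 0)) stop("zero expected count")
  structure(list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, pr = ht$residuals, expected = ht$expected,
                 factor_a = if (inherits(ct, "contingency_table")) ct$factor_a else NA,
                 factor_b = if (inherits(ct, "contingency_table")) ct$factor_b else NA),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-squared: X2 = %.2f, df = %d, P = %.3g  (%s x %s)\n",
              x$chi2, x$df, x$p, x$factor_a, x$factor_b))
  invisible(x)
}

#' Association tests for every pair of factors
#'
#' @inheritParams build_contingency
#' @param factors factor names to scan (default all).
#' @return list of `association_result`, one per unordered factor pair,
#'   named `"a x b"`.
#' @export
association_scan <- function(ft, factors = names(ft$factors),
                             merges = character(), exclusions = character()) {
  pairs <- utils::combn(factors, 2L)
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    ct <- build_contingency(ft, pairs[1, j], pairs[2, j], merges, exclusions)
    out[[paste(pairs[1, j], "x", pairs[2, j])]] <- chi_squared(ct)
  }
  out
}

#' Tidy table of association-scan results
#'
#' @param results list from [association_scan()].
#' @return data frame with columns `factor_a`, `factor_b`, `chi2`, `df`, `p`.
#' @export
association_table <- function(results) {
  data.frame(factor_a = vapply(results, `[[`, character(1), "factor_a"),
             factor_b = vapply(results, `[[`, character(1), "factor_b"),
             chi2 = vapply(results, `[[`, numeric(1), "chi2"),
             df = vapply(results, `[[`, numeric(1), "df"),
             p = vapply(results, `[[`, numeric(1), "p"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Significant category-pair association edges
#'
#' For every factor pair whose chi-squared test is significant at `alpha`,
#' each category pair with `|Pearson residual| >= pr_threshold` becomes an
#' edge, signed by the residual (positive = the categories co-occur more
#' often than expected). The default threshold 2 corresponds roughly to a
#' standard-normal residual at the 5% level.
#'
#' @param results list of `association_result` (from [association_scan()]).
#' @param alpha significance level for the factor-pair test.
#' @param pr_threshold minimal absolute Pearson residual for an edge.
#' @return data frame with columns `cat_a`, `cat_b`, `factor_a`, `factor_b`,
#'   `sign` (+1/-1), `weight` (`|pr|`), `pr`.
#' @export
association_edges <- function(results, alpha = 0.05, pr_threshold = 2) {
  rows <- list()
  for (res in results) {
    if (res$p >= alpha) next
    hit <- which(abs(res$pr) >= pr_threshold, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      pr <- res$pr[hit[h, 1], hit[h, 2]]
      rows[[length(rows) + 1L]] <- data.frame(
        cat_a = rownames(res$pr)[hit[h, 1]],
        cat_b = colnames(res$pr)[hit[h, 2]],
        factor_a = res$factor_a, factor_b = res$factor_b,
        sign = sign(pr), weight = abs(pr), pr = pr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cat_a = character(), cat_b = character(),
                      factor_a = character(), factor_b = character(),
                      sign = numeric(), weight = numeric(), pr = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Distance matrix between categories from Pearson-residual profiles
#'
#' Each category is described by the profile of its Pearson residuals
#' against all categories of the other factors. Residuals can be negative,
#' so all profiles are shifted to non-negative values by subtracting the
#' global minimum before Bray-Curtis dissimilarities are computed between
#' profiles (over the profile coordinates defined for both categories;
#' residuals between categories of the same factor do not exist). A pair of
#' all-zero shifted profiles has distance 0.
#'
#' @param results list of `association_result` covering every factor pair.
#' @return symmetric category-by-category distance matrix with zero
#'   diagonal.
#' @export
pr_profile_distance <- function(results) {
  # assemble the full category x category PR matrix (NA within a factor)
  cats <- list()
  for (res in results) {
    cats[[res$factor_a]] <- rownames(res$pr)
    cats[[res$factor_b]] <- colnames(res$pr)
  }
  all_cats <- unlist(cats, use.names = FALSE)
  if (anyDuplicated(all_cats))
    stop("category labels must be unique across factors")
  M <- matrix(NA_real_, length(all_cats), length(all_cats),
              dimnames = list(all_cats, all_cats))
  for (res in results) {
    M[rownames(res$pr), colnames(res$pr)] <- res$pr
    M[colnames(res$pr), rownames(res$pr)] <- t(res$pr)
  }
  shift <- min(M, na.rm = TRUE)
  M <- M - shift
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = dimnames(M))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(M[i, ]) & !is.na(M[j, ])
    x <- M[i, ok]; y <- M[j, ok]
    denom <- sum(x + y)
    D[i, j] <- D[j, i] <- if (denom == 0) 0 else sum(abs(x - y)) / denom
  }
  D
}

#' NMDS embedding of the category association network
#'
#' Non-metric multidimensional scaling (monotone regression, Kruskal
#' stress-1) of the Pearson-residual profile distances, so that positively
#' associated categories fall close together. Best solution over
#' `n_starts` random starts; coordinates are centred and scaled to unit
#' root-mean-square point norm. Deterministic given `seed`.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [pr_profile_distance()]).
#' @param k embedding dimension.
#' @param n_starts random starts handed to [vegan::metaMDS()].
#' @param seed integer seed.
#' @param edges optional edge data frame (from [association_edges()]) to
#'   attach to the embedding.
#' @return object of class `network_embedding`: list with `coordinates`
#'   (matrix, one row per category), `stress`, `converged`, `edges`.
#' @export
nmds_embed <- function(d, k = 2, n_starts = 20, seed = NULL, edges = NULL) {
  set_seed_if(seed)
  fit <- vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts,
                        trace = 0, autotransform = FALSE, wascores = FALSE)
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge; returning best solution found ",
            sprintf("(stress %.4f)", fit$stress))
  xy <- vegan::scores(fit, display = "sites")
  xy <- sweep(xy, 2, colMeans(xy))
  rms <- sqrt(mean(rowSums(xy^2)))
  if (rms > 0) xy <- xy / rms
  structure(list(coordinates = xy, stress = fit$stress,
                 converged = isTRUE(fit$converged), edges = edges),
            class = "network_embedding")
}

#' @export
print.network_embedding <- function(x, ...) {
  cat(sprintf("NMDS embedding: %d categories in %d dimensions, stress = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  if (!is.null(x$edges))
    cat("  edges:", sum(x$edges$sign > 0), "positive,",
        sum(x$edges$sign < 0), "negative\n")
  invisible(x)
}

#' Clusters of positively associated categories
#'
#' Connected components of the graph whose vertices are categories and whose
#' edges are the significant positive associations. Components with a single
#' category are dropped.
#'
#' @param edges edge data frame from [association_edges()].
#' @return list of character vectors, one per cluster, largest first.
#' @export
network_clusters <- function(edges) {
  pos <- edges[edges$sign > 0, , drop = FALSE]
  if (nrow(pos) == 0L) return(list())
  g <- igraph::graph_from_data_frame(pos[, c("cat_a", "cat_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  out <- split(names(comp$membership), comp$membership)
  out <- out[lengths(out) > 1L]
  names(out) <- NULL
  out[order(-lengths(out))]
}
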