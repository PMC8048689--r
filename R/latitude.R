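## 10-degree latitudinal bins: half-open [lower, upper), 18 bins covering
## [-90, 90). A record at exactly +90 is folded into the top bin.

lat_bin_table <- function(width = 10) {
  lower <- seq(-90, 90 - width, by = width)
  data.frame(bin = seq_along(lower), lower = lower, upper = lower + width,
             mid = lower + width / 2)
}

#' Latitudinal presence profile from occurrence records
#'
#' Assigns every species to the latitude bins its records fall in
#' (half-open intervals `[lower, upper)`). By default presence is
#' record-based: a species with records at -12 and +23 is present in the
#' two corresponding bins only. With `range_fill = TRUE` all bins between a
#' species' extreme records are marked present (a coarse stand-in for range
#' maps).
#'
#' @param occ an [occurrence_table()].
#' @param width bin width in degrees (default 10, giving 18 bins).
#' @param min_records minimal number of records in a bin for presence.
#' @param range_fill fill all bins between the extreme records of each
#'   species.
#' @return object of class `lat_profile`: list with `bins` (data frame:
#'   `bin`, `lower`, `upper`, `mid`, `richness`), `present` (list of
#'   species character vectors, one per bin) and `species` (all species
#'   seen).
#' @export
bin_presence <- function(occ, width = 10, min_records = 1L,
                         range_fill = FALSE) {
  if (nrow(occ) == 0L) stop("no occurrence records")
  bins <- lat_bin_table(width)
  nb <- nrow(bins)
  bin_of <- pmin(findInterval(occ$latitude, c(bins$lower, 90)), nb)
  present <- vector("list", nb)
  counts <- table(factor(bin_of, levels = seq_len(nb)), occ$species)
  for (b in seq_len(nb))
    present[[b]] <- colnames(counts)[counts[b, ] >= min_records]
  if (range_fill) {
    for (sp in unique(occ$species)) {
      hit <- which(vapply(present, function(s) sp %in% s, logical(1)))
      if (length(hit) > 1L)
        for (b in seq(min(hit), max(hit)))
          present[[b]] <- union(present[[b]], sp)
    }
  }
  bins$richness <- lengths(present)
  structure(list(bins = bins, present = present,
                 species = sort(unique(occ$species))),
            class = "lat_profile")
}

#' Per-bin disparity of a latitudinal profile
#'
#' Computes the mean pairwise dissimilarity of the species present in each
#' latitude bin. Bins with fewer than 2 species (or species absent from the
#' distance matrix) are undefined.
#'
#' @param profile a `lat_profile` from [bin_presence()].
#' @param dm a `dist_matrix`.
#' @return the profile with an added `disparity` element (list of
#'   `disparity_estimate` per bin) and `bins` columns `disparity`,
#'   `disparity_sd`.
#' @export
profile_disparity <- function(profile, dm) {
  est <- lapply(profile$present, function(sp)
    group_disparity(dm, intersect(sp, dm$taxa)))
  profile$disparity <- est
  profile$bins$disparity <- vapply(est, `[[`, numeric(1), "mean")
  profile$bins$disparity_sd <- vapply(est, `[[`, numeric(1), "sd")
  profile
}

#' @export
print.lat_profile <- function(x, ...) {
  cat("lat_profile:", nrow(x$bins), "bins,", length(x$species), "species\n")
  occupied <- x$bins[x$bins$richness > 0, ]
  cat("  occupied bins:", nrow(occupied), "; max richness",
      max(x$bins$richness), "at [", occupied$lower[which.max(occupied$richness)],
      ",", occupied$upper[which.max(occupied$richness)], ")\n")
  invisible(x)
}

#' Correlation and regression of a bin response against latitude
#'
#' Pearson correlation (two-sided t-based p) and ordinary least squares of
#' per-bin richness or disparity against the absolute bin midpoint
#' (distance from the Equator), or of disparity against richness. Bins
#' without a defined response are excluded; bins with richness at or below
#' `min_richness` can be excluded to probe the influence of species-poor
#' intervals.
#'
#' @param profile a `lat_profile` (with disparity added for
#'   `response = "disparity"`).
#' @param response `"richness"` or `"disparity"`.
#' @param covariate `"abs_latitude"` (default) or `"richness"`.
#' @param min_richness optional; bins with richness `<= min_richness` are
#'   dropped.
#' @return object of class `gradient_stats`: list with `r`, `p`, `slope`,
#'   `intercept`, `n_bins`, `response`, `covariate`.
#' @export
gradient_stats <- function(profile, response = c("richness", "disparity"),
                           covariate = c("abs_latitude", "richness"),
                           min_richness = NULL) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  b <- profile$bins
  y <- switch(response, richness = b$richness, disparity = b$disparity)
  if (is.null(y)) stop("profile has no ", response, " values")
  x <- switch(covariate, abs_latitude = abs(b$mid), richness = b$richness)
  keep <- b$richness > 0 & !is.na(y) & !is.na(x)
  if (!is.null(min_richness)) keep <- keep & b$richness > min_richness
  x <- x[keep]; y <- y[keep]
  if (length(y) < 3L) stop("fewer than 3 usable bins")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    warning("zero variance in ", if (stats::sd(y) == 0) response else covariate,
            "; correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                          intercept = NA_real_, n_bins = length(y),
                          response = response, covariate = covariate),
                     class = "gradient_stats"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_bins = length(y), response = response,
                 covariate = covariate),
            class = "gradient_stats")
}

#' @export
print.gradient_stats <- function(x, ...) {
  cat(sprintf("%s vs %s over %d bins: r = %.3f, P = %.3g; OLS intercept %.4g, slope %.4g\n",
              x$response, x$covariate, x$n_bins, x$r, x$p, x$intercept, x$slope))
  invisible(x)
}

#' Richness-controlled null envelope for per-bin disparity
#'
#' Tests whether per-bin disparity merely tracks per-bin richness: for each
#' bin with at least 2 species, `n_draws` random species sets of the same
#' size are drawn uniformly from the full species pool and their mean
#' pairwise dissimilarity computed. The observed bin disparity is compared
#' with this null via its 2.5%/97.5% envelope and a two-sided empirical
#' p-value (tie-inclusive count / `n_draws`, doubled and capped at 1).
#'
#' @param profile a `lat_profile` with disparity (see
#'   [profile_disparity()]).
#' @param dm a `dist_matrix`; its taxa are the resampling pool.
#' @param n_draws random sets per bin.
#' @param seed integer seed.
#' @return data frame with one row per bin: `bin`, `lower`, `upper`,
#'   `richness`, `observed`, `null_mean`, `q025`, `q975`, `p_emp`
#'   (`NA` for bins with fewer than 2 species).
#' @export
richness_controlled_null <- function(profile, dm, n_draws = 10000,
                                     seed = NULL) {
  set_seed_if(seed)
  pool <- dm$taxa
  npool <- length(pool)
  d <- dm$d
  out <- profile$bins[, c("bin", "lower", "upper", "richness")]
  out$observed <- profile$bins$disparity
  out$null_mean <- out$q025 <- out$q975 <- out$p_emp <- NA_real_
  for (b in seq_len(nrow(out))) {
    sp <- intersect(profile$present[[b]], pool)
    nb <- length(sp)
    if (nb < 2L || nb > npool) next
    obs <- out$observed[b]
    null_vals <- vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(npool, nb)
      within_mean(d, idx)
    }, numeric(1))
    qs <- stats::quantile(null_vals, c(0.025, 0.975), names = FALSE)
    p_lo <- mean(null_vals <= obs)
    p_hi <- mean(null_vals >= obs)
    out$null_mean[b] <- mean(null_vals)
    out$q025[b] <- qs[1]; out$q975[b] <- qs[2]
    out$p_emp[b] <- min(1, 2 * min(p_lo, p_hi))
  }
  out
}
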