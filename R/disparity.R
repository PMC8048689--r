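#' Disparity of a group: mean pairwise dissimilarity
#'
#' Disparity of a set of taxa is the mean of all defined pairwise mean
#' character differences among them; the accompanying SD is the sample
#' (n - 1) standard deviation of those pairwise values, describing the
#' spread of the pairwise-distance distribution. The mean pairwise
#' dissimilarity is insensitive to group size, which makes groups of very
#' different sizes comparable.
#'
#' @param dm a `dist_matrix` from [distance_matrix()].
#' @param members character vector of taxa (subset of `dm$taxa`).
#' @return an object of class `disparity_estimate`: list with `mean`, `sd`,
#'   `n_taxa`, `n_pairs` and logical `defined` (`FALSE` when fewer than 2
#'   members).
#' @export
group_disparity <- function(dm, members) {
  members <- unique(as.character(members))
  if (!all(members %in% dm$taxa))
    stop("unknown taxa: ",
         paste(setdiff(members, dm$taxa), collapse = ", "))
  n <- length(members)
  if (n < 2L)
    return(structure(list(mean = NA_real_, sd = NA_real_, n_taxa = n,
                          n_pairs = 0L, defined = FALSE),
                     class = "disparity_estimate"))
  idx <- match(members, dm$taxa)
  v <- pairwise_values(dm$d, idx)
  v <- v[!is.na(v)]
  structure(list(mean = mean(v),
                 sd = if (length(v) > 1L) stats::sd(v) else 0,
                 n_taxa = n, n_pairs = length(v),
                 defined = length(v) > 0L),
            class = "disparity_estimate")
}

#' @export
print.disparity_estimate <- function(x, ...) {
  if (!x$defined) {
    cat("disparity_estimate: undefined (n_taxa =", x$n_taxa, ")\n")
  } else {
    cat(sprintf("disparity_estimate: D-bar = %.4f +/- %.4f (n_taxa = %d, n_pairs = %d)\n",
                x$mean, x$sd, x$n_taxa, x$n_pairs))
  }
  invisible(x)
}

#' Disparity per category of one factor
#'
#' Descriptive disparity: a taxon belonging to several categories of the
#' factor contributes to every one of them; taxa with a missing factor value
#' are excluded. Categories with no member are skipped with a warning.
#'
#' @param dm a `dist_matrix`.
#' @param ft a [factor_table()].
#' @param factor name of the factor.
#' @return named list of `disparity_estimate`, one per category (vocabulary
#'   order).
#' @export
disparity_by_category <- function(dm, ft, factor) {
  if (!factor %in% names(ft$factors))
    stop("unknown factor: ", factor)
  fk <- match(factor, names(ft$factors))
  taxa <- intersect(dm$taxa, ft$taxa)
  out <- list()
  for (cat in ft$factors[[factor]]) {
    members <- taxa[vapply(taxa, function(tx)
      cat %in% ft$cells[[match(tx, ft$taxa), fk]], logical(1))]
    if (length(members) == 0L) {
      warning("category '", cat, "' of factor '", factor,
              "' has no members; skipped")
      next
    }
    out[[cat]] <- group_disparity(dm, members)
  }
  out
}

#' Tidy data frame of per-category disparity
#'
#' @param x named list of `disparity_estimate` (from
#'   [disparity_by_category()]).
#' @return data frame with columns `category`, `n_taxa`, `n_pairs`, `mean`,
#'   `sd`.
#' @export
disparity_table <- function(x) {
  data.frame(category = names(x),
             n_taxa = vapply(x, `[[`, integer(1), "n_taxa"),
             n_pairs = vapply(x, `[[`, integer(1), "n_pairs"),
             mean = vapply(x, `[[`, numeric(1), "mean"),
             sd = vapply(x, `[[`, numeric(1), "sd"),
             row.names = NULL, stringsAsFactors = FALSE)
}
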