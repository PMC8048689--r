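#' Randomly resolve polymorphism in a morphological matrix
#'
#' The mean character difference is defined for monomorphic cells only, so a
#' polymorphism-free matrix is sampled before every distance computation:
#' every polymorphic cell is replaced by one member of its state set drawn
#' uniformly at random. Missing cells are unchanged. Deterministic given
#' `seed`.
#'
#' @param m a [morph_matrix()].
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @return a `morph_matrix` with all cells of size 0 or 1.
#' @export
resolve_morph_polymorphism <- function(m, seed = NULL) {
  set_seed_if(seed)
  cells <- m$cells
  poly <- which(lengths(cells) > 1L)
  for (idx in poly) {
    st <- cells[[idx]]
    cells[[idx]] <- st[sample.int(length(st), 1L)]
  }
  m$cells <- cells
  m
}

## Encode a resolved (monomorphic) matrix as a numeric taxa x characters
## matrix plus per-character kind and span vectors. Categorical states are
## encoded by their index in the state vocabulary (= rank for ordered
## characters), continuous cells by their value; missing cells are NA.
encode_resolved <- function(m) {
  if (any(lengths(m$cells) > 1L))
    stop("matrix still contains polymorphic cells; resolve first")
  n <- length(m$taxa); p <- length(m$defs)
  X <- matrix(NA_real_, n, p, dimnames = list(m$taxa, names(m$defs)))
  kind <- vapply(m$defs, `[[`, character(1), "kind")
  span <- vapply(m$defs, `[[`, numeric(1), "range_span")
  for (k in seq_len(p)) {
    col <- m$cells[, k]
    scored <- lengths(col) == 1L
    vals <- unlist(col[scored], use.names = FALSE)
    X[scored, k] <- if (kind[k] == "continuous") vals
      else match(vals, m$defs[[k]]$state_labels)
  }
  list(X = X, kind = kind, span = span)
}

## per-character dissimilarity contribution between two encoded values
char_diff <- function(a, b, kind, span) {
  switch(kind,
    binary = ,
    unordered = as.numeric(a != b),
    ordered = ,
    continuous = if (span == 0) 0 else abs(a - b) / span)
}

#' Mean character difference between two taxa
#'
#' Gower-type dissimilarity over the characters scored in both taxa:
#' binary and unordered characters contribute a 0/1 mismatch, ordered
#' characters the absolute rank difference divided by the observed rank span,
#' continuous characters the absolute difference divided by the observed
#' range. Characters missing in either taxon are excluded from numerator and
#' denominator. Rows must be monomorphic (resolve polymorphism first).
#'
#' @param a,b named lists of singleton state sets (rows of a resolved
#'   `morph_matrix`, e.g. `m$cells[1, ]`).
#' @param defs list of [character_definition()] with recomputed spans.
#' @return list with elements `D` (mean character difference, `NA` when no
#'   character is shared) and `n_shared` (number of characters scored in
#'   both taxa).
#' @export
pair_distance <- function(a, b, defs) {
  stopifnot(length(a) == length(defs), length(b) == length(defs))
  num <- 0; n_shared <- 0L
  for (k in seq_along(defs)) {
    sa <- a[[k]]; sb <- b[[k]]
    if (length(sa) != 1L || length(sb) != 1L) {
      if (length(sa) > 1L || length(sb) > 1L)
        stop("polymorphic cell in pair_distance; resolve first")
      next
    }
    def <- defs[[k]]
    ea <- if (def$kind == "continuous") sa else match(sa, def$state_labels)
    eb <- if (def$kind == "continuous") sb else match(sb, def$state_labels)
    num <- num + char_diff(ea, eb, def$kind, def$range_span)
    n_shared <- n_shared + 1L
  }
  list(D = if (n_shared > 0L) num / n_shared else NA_real_,
       n_shared = n_shared)
}

#' Mean character difference distance matrix
#'
#' Resolves polymorphism (with `seed`), then computes the mean character
#' difference for every pair of taxa. Pairs sharing no scored character are
#' undefined (`NA`) and reported with a warning.
#'
#' @inheritParams resolve_morph_polymorphism
#' @return an object of class `dist_matrix`: list with `taxa`, `d` (symmetric
#'   matrix in \[0, 1\], zero diagonal) and `n_shared` (symmetric count
#'   matrix).
#' @export
distance_matrix <- function(m, seed = NULL) {
  if (length(m$taxa) < 2L) stop("need at least 2 taxa")
  mr <- resolve_morph_polymorphism(m, seed)
  enc <- encode_resolved(mr)
  n <- nrow(enc$X)
  num <- matrix(0, n, n)
  den <- matrix(0L, n, n)
  for (k in seq_len(ncol(enc$X))) {
    v <- enc$X[, k]
    obs <- !is.na(v)
    if (!any(obs)) next
    contrib <- if (enc$kind[k] %in% c("binary", "unordered")) {
      outer(v, v, "!=") * 1
    } else if (enc$span[k] == 0) {
      matrix(0, n, n)
    } else {
      abs(outer(v, v, "-")) / enc$span[k]
    }
    contrib[!obs, ] <- 0; contrib[, !obs] <- 0
    num <- num + contrib
    den <- den + outer(obs, obs, "&")
  }
  d <- ifelse(den > 0L, num / den, NA_real_)
  diag(d) <- 0
  dimnames(d) <- dimnames(den) <- list(m$taxa, m$taxa)
  undef <- which(den == 0L & upper.tri(den), arr.ind = TRUE)
  if (nrow(undef))
    warning("undefined distance for ", nrow(undef), " pair(s): ",
            paste(m$taxa[undef[, 1]], m$taxa[undef[, 2]], sep = "--",
                  collapse = ", "))
  structure(list(taxa = m$taxa, d = d, n_shared = den), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  v <- pairwise_values(x$d)
  cat("dist_matrix:", length(x$taxa), "taxa;",
      sum(is.na(v)), "undefined pair(s)\n")
  cat(sprintf("  mean D = %.4f, range [%.4f, %.4f]\n",
              mean(v, na.rm = TRUE), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Write / read a distance matrix as square labelled text
#'
#' @param dm a `dist_matrix`.
#' @param path output/input path.
#' @param sep field separator.
#' @return `write_distance_matrix()` the path invisibly;
#'   `read_distance_matrix()` a `dist_matrix` (with `n_shared` unknown,
#'   set to `NA`).
#' @export
write_distance_matrix <- function(dm, path, sep = "\t") {
  out <- data.frame(taxon = dm$taxa, dm$d, check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, sep = NULL) {
  df <- read_delim_chr(path, sep)
  taxa <- df[[1]]
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(taxa, taxa)
  structure(list(taxa = taxa, d = d,
                 n_shared = matrix(NA_integer_, length(taxa), length(taxa))),
            class = "dist_matrix")
}
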