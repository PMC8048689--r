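# Fixture builders and independent oracles used across the test files.

## list-matrix constructor from a plain character matrix of encoded cells
## ("a/b" = polymorphic, "?" = missing); continuous columns are parsed to
## numeric
cells_from_strings <- function(chr, defs) {
  cells <- matrix(vector("list", length(chr)), nrow(chr), ncol(chr))
  for (k in seq_len(ncol(chr))) {
    numeric <- defs[[k]]$kind == "continuous"
    for (i in seq_len(nrow(chr))) {
      x <- chr[i, k]
      cells[[i, k]] <-
        if (x == "?") (if (numeric) numeric(0) else character(0))
        else if (numeric) as.numeric(strsplit(x, "/", fixed = TRUE)[[1]])
        else strsplit(x, "/", fixed = TRUE)[[1]]
    }
  }
  colnames(cells) <- vapply(defs, `[[`, character(1), "character_id")
  cells
}

make_morph <- function(chr, defs, taxa = paste0("t", seq_len(nrow(chr)))) {
  morph_matrix(cells_from_strings(chr, defs), defs, taxa)
}

## quick factor_table from a named list of per-factor character vectors;
## "a/b" = multi-membership, "?" = missing
make_ft <- function(..., taxa = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  taxa <- taxa %||% paste0("t", seq_len(n))
  cells <- matrix(vector("list", n * length(cols)), n, length(cols),
                  dimnames = list(taxa, names(cols)))
  for (k in seq_along(cols)) for (i in seq_len(n)) {
    x <- cols[[k]][i]
    cells[[i, k]] <- if (x == "?") character(0)
                     else strsplit(x, "/", fixed = TRUE)[[1]]
  }
  factor_table(cells, vocab = NULL, taxa = taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap a plain symmetric matrix as the package's dist_matrix container
as_dist_matrix <- function(d, taxa = paste0("t", seq_len(nrow(d)))) {
  d <- as.matrix(d)
  dimnames(d) <- list(taxa, taxa)
  structure(list(taxa = taxa, d = d,
                 n_shared = matrix(1L, nrow(d), nrow(d))),
            class = "dist_matrix")
}

## ---- independent brute-force distance oracle ---------------------------
## direct double loop over characters, written against the definition and
## sharing no code with distance_matrix()
oracle_pair <- function(m, i, j) {
  num <- 0; n <- 0L
  for (k in seq_along(m$defs)) {
    a <- m$cells[[i, k]]; b <- m$cells[[j, k]]
    if (length(a) != 1L || length(b) != 1L) next
    def <- m$defs[[k]]
    dk <- if (def$kind %in% c("binary", "unordered")) {
      if (a == b) 0 else 1
    } else if (def$kind == "ordered") {
      if (def$range_span == 0) 0 else
        abs(match(a, def$state_labels) - match(b, def$state_labels)) /
          def$range_span
    } else {
      if (def$range_span == 0) 0 else abs(a - b) / def$range_span
    }
    num <- num + dk; n <- n + 1L
  }
  c(D = if (n > 0) num / n else NA_real_, n_shared = n)
}

oracle_distance_matrix <- function(m) {
  n <- length(m$taxa)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- oracle_pair(m, i, j)["D"]
  }
  dimnames(d) <- list(m$taxa, m$taxa)
  d
}

## random monomorphic mixed-type fixture (optionally with missing cells)
random_fixture <- function(n_taxa, seed, missing_frac = 0.15) {
  set.seed(seed)
  defs <- list(
    character_definition("b1", "binary", c("0", "1")),
    character_definition("b2", "binary", c("a", "p")),
    character_definition("u1", "unordered", c("x", "y", "z")),
    character_definition("u2", "unordered", c("s1", "s2", "s3", "s4")),
    character_definition("o1", "ordered", c("0", "1", "2", "3")),
    character_definition("o2", "ordered", c("lo", "mid", "hi")),
    character_definition("c1", "continuous"),
    character_definition("c2", "continuous"))
  n <- n_taxa
  cells <- matrix(vector("list", n * length(defs)), n, length(defs))
  for (k in seq_along(defs)) for (i in seq_len(n)) {
    cells[[i, k]] <- if (runif(1) < missing_frac) {
      if (defs[[k]]$kind == "continuous") numeric(0) else character(0)
    } else if (defs[[k]]$kind == "continuous") {
      round(rnorm(1), 3)
    } else {
      sample(defs[[k]]$state_labels, 1)
    }
  }
  colnames(cells) <- vapply(defs, `[[`, character(1), "character_id")
  morph_matrix(cells, defs, paste0("t", seq_len(n)))
}

## ---- exhaustive permutation oracles ------------------------------------
## every distinct two-group assignment of n taxa (n1 in group A)
all_splits <- function(n, n1) {
  combn(n, n1, simplify = FALSE)
}

oracle_within_mean <- function(d, idx) {
  v <- d[idx, idx][upper.tri(diag(length(idx)))]
  mean(v)
}

## exact permutation p for the two-group ANOVA (enumeration over all splits)
oracle_anova_p <- function(d, n1) {
  n <- nrow(d)
  f_of <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    A <- d^2
    ss_tot <- sum(A) / (2 * n)
    ss_w <- sum(A[ia, ia]) / (2 * length(ia)) +
      sum(A[ib, ib]) / (2 * length(ib))
    if (ss_w == 0) return(Inf)
    ((ss_tot - ss_w) / 1) / (ss_w / (n - 2))
  }
  f_obs <- f_of(seq_len(n1))
  fs <- vapply(all_splits(n, n1), f_of, numeric(1))
  mean(fs >= f_obs)
}

## exact two-sided p for the central-tendency statistic
oracle_ct_p <- function(d, n1) {
  n <- nrow(d)
  t_of <- function(ia) {
    ib <- setdiff(seq_len(n), ia)
    oracle_within_mean(d, ia) - oracle_within_mean(d, ib)
  }
  t_obs <- t_of(seq_len(n1))
  ts <- vapply(all_splits(n, n1), t_of, numeric(1))
  mean(abs(ts) >= abs(t_obs))
}
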