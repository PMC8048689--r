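# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministically derive independent sub-seeds from one base seed.
## Keeps every derived seed in 32-bit integer range.
spawn_seeds <- function(base_seed, n) {
  stopifnot(length(base_seed) == 1L, is.finite(base_seed))
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

## mean/sd of the upper triangle of a (sub)matrix of pairwise distances,
## ignoring undefined (NA) pairs
pairwise_values <- function(d, idx = NULL) {
  if (!is.null(idx)) d <- d[idx, idx, drop = FALSE]
  d[upper.tri(d)]
}

is_wholenumber <- function(x, tol = 1e-8) abs(x - round(x)) < tol
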