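#' Character definition for a morphological matrix
#'
#' Describes one column of a morphological matrix: its identifier, its
#' measurement kind and, for categorical characters, the ordered vocabulary of
#' state labels. The scaling span (`range_span`) used by the mean character
#' difference is always recomputed from the observed data when a matrix is
#' assembled, so the value supplied here is only a placeholder.
#'
#' @param character_id short character scalar naming the character.
#' @param kind one of `"binary"`, `"unordered"`, `"ordered"`, `"continuous"`.
#' @param state_labels character vector of state labels; for `"ordered"`
#'   characters the order of this vector defines the rank order. Must be
#'   empty for `"continuous"` characters.
#' @param range_span numeric scalar; observed span used for range scaling
#'   (recomputed from data by [morph_matrix()]).
#' @return an object of class `character_definition`.
#' @export
character_definition <- function(character_id, kind,
                                 state_labels = character(),
                                 range_span = NA_real_) {
  kind <- match.arg(kind, c("binary", "unordered", "ordered", "continuous"))
  stopifnot(is.character(character_id), length(character_id) == 1L,
            nzchar(character_id))
  state_labels <- as.character(state_labels)
  if (kind == "continuous" && length(state_labels) > 0L)
    stop("continuous character '", character_id, "' must not have state labels")
  if (kind == "binary" && length(state_labels) != 2L)
    stop("binary character '", character_id, "' must have exactly 2 state labels")
  if (kind %in% c("unordered", "ordered") && length(state_labels) < 2L)
    stop(kind, " character '", character_id, "' must have at least 2 state labels")
  if (anyDuplicated(state_labels))
    stop("duplicated state labels for character '", character_id, "'")
  structure(
    list(character_id = character_id, kind = kind,
         state_labels = state_labels, range_span = as.numeric(range_span)),
    class = "character_definition")
}

#' Morphological matrix of mixed-type characters
#'
#' A taxa-by-characters table in which every cell holds a *state set*: an
#' empty set encodes missing data, a singleton a monomorphic score and a set
#' with more than one element a polymorphic score. Categorical cells hold
#' character vectors of state labels, continuous cells numeric vectors
#' (several values = several measurements, treated as polymorphism).
#'
#' `range_span` of every ordered and continuous character is recomputed from
#' the observed data (maximum minus minimum observed rank or value across the
#' whole dataset) so that per-character scaling in the distance is shared by
#' all downstream group comparisons.
#'
#' @param cells a `list`-mode matrix (taxa in rows, characters in columns);
#'   each element a character vector (categorical) or numeric vector
#'   (continuous), possibly empty.
#' @param defs list of [character_definition()] objects, one per column.
#' @param taxa character vector of unique taxon identifiers, one per row.
#' @return an object of class `morph_matrix` with elements `taxa`, `defs`,
#'   `cells`.
#' @export
morph_matrix <- function(cells, defs, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) == 0L) stop("empty matrix: no taxa")
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifier(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (!is.matrix(cells) || !is.list(cells))
    stop("cells must be a list-mode matrix")
  if (nrow(cells) != length(taxa)) stop("cells/taxa dimension mismatch")
  if (ncol(cells) != length(defs)) stop("cells/defs dimension mismatch")
  ids <- vapply(defs, function(d) d$character_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate character ids")
  names(defs) <- ids
  dimnames(cells) <- list(taxa, ids)

  # validate states and recompute spans from the observed data
  for (k in seq_along(defs)) {
    def <- defs[[k]]
    col <- cells[, k]
    if (def$kind == "continuous") {
      vals <- unlist(col, use.names = FALSE)
      if (length(vals) && !is.numeric(vals))
        stop("non-numeric value in continuous character '", def$character_id, "'")
      defs[[k]]$range_span <-
        if (length(vals)) max(vals) - min(vals) else 0
    } else {
      for (i in seq_along(col)) {
        st <- col[[i]]
        bad <- setdiff(st, def$state_labels)
        if (length(bad))
          stop("unknown state '", bad[1], "' for taxon '", taxa[i],
               "', character '", def$character_id, "'")
      }
      if (def$kind == "ordered") {
        obs <- unlist(col, use.names = FALSE)
        ranks <- match(obs, def$state_labels)
        defs[[k]]$range_span <-
          if (length(ranks)) max(ranks) - min(ranks) else 0
      } else {
        defs[[k]]$range_span <- NA_real_
      }
    }
  }
  structure(list(taxa = taxa, defs = defs, cells = cells),
            class = "morph_matrix")
}

#' Taxa-by-factors table with multi-membership
#'
#' Each cell holds the set of categories a taxon belongs to for one factor
#' (growth form, habitat, climate, region, ...). Empty set = missing; more
#' than one category = multi-membership (factor polymorphism).
#'
#' @param cells a `list`-mode matrix (taxa in rows, factors in columns) of
#'   character vectors.
#' @param vocab named list, one character vector of admissible categories per
#'   factor. If `NULL`, vocabularies are collected from the data.
#' @param taxa character vector of unique taxon identifiers.
#' @return an object of class `factor_table` with elements `taxa`, `factors`
#'   (named vocab list) and `cells`.
#' @export
factor_table <- function(cells, vocab = NULL, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) == 0L) stop("empty factor table")
  if (anyDuplicated(taxa)) stop("duplicate taxon identifier(s)")
  if (!is.matrix(cells) || !is.list(cells)) stop("cells must be a list-mode matrix")
  fnames <- colnames(cells)
  if (is.null(fnames) || any(!nzchar(fnames))) stop("factors must be named")
  if (is.null(vocab)) {
    vocab <- lapply(seq_len(ncol(cells)), function(k)
      sort(unique(unlist(cells[, k], use.names = FALSE))))
    names(vocab) <- fnames
  }
  for (k in seq_len(ncol(cells))) {
    vals <- unlist(cells[, k], use.names = FALSE)
    if (length(vals) == 0L)
      stop("factor '", fnames[k], "' has no scored cells")
    bad <- setdiff(vals, vocab[[fnames[k]]])
    if (length(bad))
      stop("category '", bad[1], "' not in vocabulary of factor '",
           fnames[k], "'")
  }
  rownames(cells) <- taxa
  structure(list(taxa = taxa, factors = vocab, cells = cells),
            class = "factor_table")
}

#' Occurrence records (species, latitude, longitude)
#'
#' @param records data frame with columns `species`, `latitude`, `longitude`
#'   (decimal degrees).
#' @return an object of class `occurrence_table` (a validated data frame).
#' @export
occurrence_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("species", "latitude", "longitude") %in% names(records)))
  records$species <- as.character(records$species)
  records$latitude <- as.numeric(records$latitude)
  records$longitude <- as.numeric(records$longitude)
  bad <- !is.finite(records$latitude) | !is.finite(records$longitude) |
    records$latitude < -90 | records$latitude > 90 |
    records$longitude < -180 | records$longitude > 180
  if (any(bad))
    stop(sum(bad), " record(s) with out-of-bounds or non-numeric coordinates; ",
         "use read_occurrences() to drop them with a warning")
  rownames(records) <- NULL
  class(records) <- c("occurrence_table", "data.frame")
  records
}

## ---- cell-set summaries -----------------------------------------------

#' Fraction of missing / polymorphic cells
#'
#' Missing = empty state set; polymorphic = state set with more than one
#' element. Fractions are taken over all cells of the table.
#'
#' @param x a `morph_matrix` or `factor_table`.
#' @return numeric scalar in \[0, 1\].
#' @export
missing_fraction <- function(x) UseMethod("missing_fraction")

#' @rdname missing_fraction
#' @export
polymorphic_fraction <- function(x) UseMethod("polymorphic_fraction")

cell_lengths <- function(x) lengths(x$cells)

#' @export
missing_fraction.morph_matrix <- function(x) mean(cell_lengths(x) == 0L)
#' @export
missing_fraction.factor_table <- function(x) mean(cell_lengths(x) == 0L)
#' @export
polymorphic_fraction.morph_matrix <- function(x) mean(cell_lengths(x) > 1L)
#' @export
polymorphic_fraction.factor_table <- function(x) mean(cell_lengths(x) > 1L)

#' @export
print.morph_matrix <- function(x, ...) {
  kinds <- table(vapply(x$defs, `[[`, character(1), "kind"))
  cat("morph_matrix:", length(x$taxa), "taxa x", length(x$defs), "characters\n")
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing cells: %.1f%%  polymorphic cells: %.1f%%\n",
              100 * missing_fraction(x), 100 * polymorphic_fraction(x)))
  invisible(x)
}

#' @export
print.factor_table <- function(x, ...) {
  cat("factor_table:", length(x$taxa), "taxa x", length(x$factors), "factors\n")
  for (f in names(x$factors))
    cat("  ", f, ": {", paste(x$factors[[f]], collapse = ", "), "}\n", sep = "")
  cat(sprintf("  missing cells: %.1f%%  multi-valued cells: %.1f%%\n",
              100 * missing_fraction(x), 100 * polymorphic_fraction(x)))
  invisible(x)
}

## category set of one taxon for one factor (character(0) if missing)
factor_cell <- function(ft, taxon, factor) {
  ft$cells[[match(taxon, ft$taxa), match(factor, names(ft$factors))]]
}

#' Taxa shared by a morphological matrix and a factor table
#'
#' Downstream analyses use the intersection of the two taxon sets; taxa
#' present in only one table are reported with a warning.
#'
#' @param m a `morph_matrix`.
#' @param ft a `factor_table`.
#' @return character vector of shared taxa (in `m`'s order).
#' @export
shared_taxa <- function(m, ft) {
  common <- intersect(m$taxa, ft$taxa)
  dropped <- length(m$taxa) + length(ft$taxa) - 2L * length(common)
  if (dropped > 0L)
    warning(dropped, " taxa present in only one of the two tables were dropped")
  if (length(common) == 0L) stop("no taxa shared between the two tables")
  m$taxa[m$taxa %in% common]
}
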