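## Delimited-text readers/writers for the three input tables.
## Dialect: header row, taxa in the first column, polymorphic cells joined
## with a separator (default "/"), missing cells a single token (default "?").

infer_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_delim_chr <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(), comment.char = "",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty table: ", path)
  df
}

parse_cell <- function(x, sep_poly = "/", na_token = "?", numeric = FALSE) {
  x <- trimws(x)
  if (!nzchar(x) || x == na_token) {
    return(if (numeric) numeric(0) else character(0))
  }
  parts <- trimws(strsplit(x, sep_poly, fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (numeric) {
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v)) return(NULL)  # caller decides how to handle
    return(v)
  }
  parts
}

format_cell <- function(st, sep_poly = "/", na_token = "?") {
  if (length(st) == 0L) return(na_token)
  out <- if (is.numeric(st)) sprintf("%.17g", st) else st  # lossless doubles
  paste(out, collapse = sep_poly)
}

#' Read character definitions
#'
#' Sidecar format: delimited text with columns `character_id`, `kind` and
#' `states` (state labels joined by `|`, in rank order for ordered
#' characters; empty for continuous characters).
#'
#' @param path path to the definitions file.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return list of [character_definition()] objects.
#' @export
read_chardefs <- function(path, sep = NULL) {
  df <- read_delim_chr(path, sep)
  need <- c("character_id", "kind", "states")
  if (!all(need %in% names(df)))
    stop("character definitions need columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    states <- df$states[i]
    labs <- if (nzchar(trimws(states)))
      trimws(strsplit(states, "|", fixed = TRUE)[[1]]) else character()
    character_definition(df$character_id[i], df$kind[i], labs)
  })
}

#' Read a morphological matrix
#'
#' @param matrix_path delimited table, taxa in the first column, one column
#'   per character.
#' @param chardef_path character-definition sidecar (see [read_chardefs()]).
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param sep_poly separator joining the states of a polymorphic cell.
#' @param na_token token encoding a missing cell.
#' @return a validated [morph_matrix()]; range spans are recomputed from the
#'   observed data.
#' @export
read_morph_matrix <- function(matrix_path, chardef_path, sep = NULL,
                              sep_poly = "/", na_token = "?") {
  defs <- read_chardefs(chardef_path, sep)
  names(defs) <- vapply(defs, `[[`, character(1), "character_id")
  df <- read_delim_chr(matrix_path, sep)
  taxa <- df[[1]]
  chars <- names(df)[-1]
  absent <- setdiff(chars, names(defs))
  if (length(absent))
    stop("no definition for character(s): ", paste(absent, collapse = ", "))
  defs <- defs[chars]
  cells <- matrix(vector("list", length(taxa) * length(chars)),
                  nrow = length(taxa), ncol = length(chars))
  for (k in seq_along(chars)) {
    numeric <- defs[[k]]$kind == "continuous"
    for (i in seq_along(taxa)) {
      cell <- parse_cell(df[[k + 1L]][i], sep_poly, na_token, numeric)
      if (is.null(cell))
        stop("non-numeric value '", df[[k + 1L]][i], "' for taxon '",
             taxa[i], "', continuous character '", chars[k], "'")
      cells[[i, k]] <- cell
    }
  }
  colnames(cells) <- chars
  m <- morph_matrix(cells, defs, taxa)
  message(sprintf(
    "read_morph_matrix: %d taxa, %d characters, %.1f%% missing, %.1f%% polymorphic",
    length(m$taxa), length(m$defs),
    100 * missing_fraction(m), 100 * polymorphic_fraction(m)))
  m
}

#' Read a factor table
#'
#' Delimited table with taxa in the first column and one column per factor;
#' multi-valued cells are joined with `sep_poly`.
#'
#' @inheritParams read_morph_matrix
#' @param path path to the table.
#' @return a validated [factor_table()]; vocabularies are collected from the
#'   observed categories.
#' @export
read_factor_table <- function(path, sep = NULL, sep_poly = "/", na_token = "?") {
  df <- read_delim_chr(path, sep)
  taxa <- df[[1]]
  fnames <- names(df)[-1]
  cells <- matrix(vector("list", length(taxa) * length(fnames)),
                  nrow = length(taxa), ncol = length(fnames),
                  dimnames = list(taxa, fnames))
  for (k in seq_along(fnames))
    for (i in seq_along(taxa))
      cells[[i, k]] <- parse_cell(df[[k + 1L]][i], sep_poly, na_token)
  ft <- factor_table(cells, vocab = NULL, taxa = taxa)
  message(sprintf(
    "read_factor_table: %d taxa, %d factors, %.1f%% missing, %.1f%% multi-valued",
    length(ft$taxa), length(ft$factors),
    100 * missing_fraction(ft), 100 * polymorphic_fraction(ft)))
  ft
}

#' Read occurrence records
#'
#' Expects columns `species`, `latitude`, `longitude`. Records with
#' non-numeric or out-of-bounds coordinates are dropped with a warning. An
#' optional per-species bounding-box filter stands in for manual curation of
#' non-native records.
#'
#' @param path path to the records table.
#' @param bbox_filter optional data frame with columns `species`, `lat_min`,
#'   `lat_max` and optionally `lon_min`, `lon_max`; records of a listed
#'   species outside its box are dropped.
#' @param taxa optional character vector of resolvable species identifiers;
#'   records of unlisted species are dropped with a message.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return an [occurrence_table()].
#' @export
read_occurrences <- function(path, bbox_filter = NULL, taxa = NULL, sep = NULL) {
  df <- read_delim_chr(path, sep)
  need <- c("species", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("occurrence table needs columns: ", paste(need, collapse = ", "))
  lat <- suppressWarnings(as.numeric(df$latitude))
  lon <- suppressWarnings(as.numeric(df$longitude))
  bad_num <- is.na(lat) | is.na(lon)
  if (any(bad_num))
    warning(sum(bad_num), " record(s) with non-numeric coordinates skipped")
  oob <- !bad_num & (lat < -90 | lat > 90 | lon < -180 | lon > 180)
  if (any(oob))
    message("read_occurrences: ", sum(oob), " out-of-bounds record(s) dropped")
  keep <- !bad_num & !oob
  rec <- data.frame(species = df$species[keep], latitude = lat[keep],
                    longitude = lon[keep], stringsAsFactors = FALSE)
  if (!is.null(taxa)) {
    unmatched <- !(rec$species %in% taxa)
    if (any(unmatched))
      message("read_occurrences: ", sum(unmatched),
              " record(s) of unknown species dropped")
    rec <- rec[!unmatched, , drop = FALSE]
  }
  if (!is.null(bbox_filter)) {
    stopifnot(all(c("species", "lat_min", "lat_max") %in% names(bbox_filter)))
    idx <- match(rec$species, bbox_filter$species)
    out <- !is.na(idx) &
      (rec$latitude < bbox_filter$lat_min[idx] |
         rec$latitude > bbox_filter$lat_max[idx])
    if (all(c("lon_min", "lon_max") %in% names(bbox_filter))) {
      out <- out | (!is.na(idx) &
                      (rec$longitude < bbox_filter$lon_min[idx] |
                         rec$longitude > bbox_filter$lon_max[idx]))
    }
    out[is.na(out)] <- FALSE
    if (any(out))
      message("read_occurrences: ", sum(out),
              " record(s) outside their species bounding box dropped")
    rec <- rec[!out, , drop = FALSE]
  }
  occurrence_table(rec)
}

## ---- writers (round-trip partners of the readers) ---------------------

#' Write tables to delimited text
#'
#' Writers matching the readers: `write_morph_matrix()` emits the matrix and
#' its character-definition sidecar, `write_factor_table()` and
#' `write_occurrences()` one table each. Reading back reproduces the cell
#' sets exactly.
#'
#' @param m,ft,occ objects to write.
#' @param matrix_path,chardef_path,path output paths.
#' @param sep field separator.
#' @param sep_poly,na_token cell-encoding conventions (see readers).
#' @return the output path(s), invisibly.
#' @export
write_morph_matrix <- function(m, matrix_path, chardef_path, sep = "\t",
                               sep_poly = "/", na_token = "?") {
  defs_df <- data.frame(
    character_id = vapply(m$defs, `[[`, character(1), "character_id"),
    kind = vapply(m$defs, `[[`, character(1), "kind"),
    states = vapply(m$defs, function(d) paste(d$state_labels, collapse = "|"),
                    character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(defs_df, chardef_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  out <- data.frame(taxon = m$taxa, stringsAsFactors = FALSE)
  for (k in seq_along(m$defs))
    out[[names(m$defs)[k]]] <-
      vapply(m$cells[, k], format_cell, character(1), sep_poly, na_token)
  utils::write.table(out, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, chardef_path))
}

#' @rdname write_morph_matrix
#' @export
write_factor_table <- function(ft, path, sep = "\t", sep_poly = "/",
                               na_token = "?") {
  out <- data.frame(taxon = ft$taxa, stringsAsFactors = FALSE)
  for (k in seq_along(ft$factors))
    out[[names(ft$factors)[k]]] <-
      vapply(ft$cells[, k], format_cell, character(1), sep_poly, na_token)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_morph_matrix
#' @export
write_occurrences <- function(occ, path, sep = "\t") {
  utils::write.table(as.data.frame(occ), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
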