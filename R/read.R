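#' Read a delimited registry table against a schema
#'
#' Reads a delimited text file with a header row, validates and one-hot
#' encodes it according to the schema, and returns a tibble of numeric
#' encoded predictor columns plus the outcome. Empty cells and "NA" are
#' treated as missing; missingness is represented by `NA` in the encoded
#' columns (the missing mask is `is.na()`). The outcome, when present, must
#' be fully observed 0/1.
#'
#' @param path Path to a delimited text file (UTF-8, header row).
#' @param schema A [registry_schema()].
#' @param delim Field delimiter, `","` by default (use `"\t"` for TSV).
#' @return A tibble of encoded columns with attributes `schema` (the
#'   encoded-column metadata), `raw_schema`, `outcome` and `strata`.
#' @export
read_registry <- function(path, schema, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  as_registry(raw, schema)
}

#' Encode an in-memory data frame against a schema
#'
#' Same validation and encoding as [read_registry()], for tables already in
#' memory.
#'
#' @param raw A data frame of raw (unencoded) columns.
#' @inheritParams read_registry
#' @return An encoded tibble; see [read_registry()].
#' @export
as_registry <- function(raw, schema) {
  stopifnot(inherits(schema, "prn_schema"))
  enc <- encode_predictors(raw, schema)
  out_col <- attr(schema, "outcome")
  strata <- attr(schema, "strata")
  if (out_col %in% names(raw)) {
    y <- as.numeric(as.character(raw[[out_col]]))
    if (anyNA(y)) abort(sprintf("Outcome column `%s` must have no missing values.", out_col))
    check_binary(y, out_col)
    enc[[out_col]] <- y
  }
  if (!is.null(strata) && strata %in% names(raw) && !strata %in% names(enc)) {
    enc[[strata]] <- raw[[strata]]
  }
  structure(enc,
            schema = encoded_columns(schema), raw_schema = schema,
            outcome = out_col, strata = strata)
}

#' Write an encoded table back to delimited text
#'
#' @param data A tibble (typically from [read_registry()] or
#'   [simulate_registry()]).
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_registry <- function(data, path, delim = ",") {
  readr::write_delim(as_tibble(data), path, delim = delim, na = "")
  invisible(path)
}

# Encoded-column metadata for a table, reconstructing it from column types
# when the table did not come through the schema path (e.g. a plain tibble
# built in code). Columns with only values in {0,1} are treated as binary.
table_schema <- function(data, outcome = attr(data, "outcome") %||% "outcome") {
  sc <- attr(data, "schema")
  cols <- predictor_cols(data, outcome)
  if (!is.null(sc)) return(sc[sc$column %in% cols, , drop = FALSE])
  kind <- vapply(cols, function(nm) {
    v <- data[[nm]]; v <- v[!is.na(v)]
    if (all(v %in% c(0, 1))) "binary" else "continuous"
  }, "")
  tibble(column = cols, kind = kind, source = cols, level = NA_character_)
}
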