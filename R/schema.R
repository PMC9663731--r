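#' Declare the column schema of a registry-like table
#'
#' A schema names each predictor and its kind (`continuous`, `binary`, or
#' `categorical` with an ordered set of levels), plus the outcome column and
#' an optional stratification column used by donor-based multiple
#' imputation. Categorical variables are one-hot encoded into named 0/1
#' indicator columns (`variable.level`), so downstream stages only ever see
#' continuous and binary encoded columns.
#'
#' @param variables A data frame (or list of lists) with columns `name`,
#'   `kind`, and optionally `levels` (list-column of level labels for
#'   categorical variables) and `units`.
#' @param outcome Name of the binary outcome column.
#' @param strata Optional name of a fully observed column used to stratify
#'   donor imputation.
#' @return A tibble of class `prn_schema` with attributes `outcome` and
#'   `strata`.
#' @examples
#' registry_schema(
#'   data.frame(name = c("age", "female"), kind = c("continuous", "binary")),
#'   outcome = "death1y"
#' )
#' @export
registry_schema <- function(variables, outcome = "outcome", strata = NULL) {
  v <- as_tibble(variables)
  if (!all(c("name", "kind") %in% names(v))) {
    abort("`variables` must have columns `name` and `kind`.")
  }
  if (anyDuplicated(v$name)) abort("Variable names must be unique.")
  bad <- setdiff(unique(v$kind), c("continuous", "binary", "categorical"))
  if (length(bad)) {
    abort(sprintf("Unknown variable kind(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"levels" %in% names(v)) v$levels <- vector("list", nrow(v))
  if (!"units" %in% names(v)) v$units <- NA_character_
  need_lv <- v$kind == "categorical" & !vapply(v$levels, length, 1L)
  if (any(need_lv)) {
    abort(sprintf("Categorical variable(s) without levels: %s",
                  paste(v$name[need_lv], collapse = ", ")))
  }
  structure(v[, c("name", "kind", "levels", "units")],
            outcome = outcome, strata = strata,
            class = c("prn_schema", class(v)))
}

#' Read a schema from a YAML configuration file
#'
#' The file declares `variables` (each with `name`, `kind`, optional
#' `levels` and `units`), the `outcome` column and optionally a `strata`
#' column.
#'
#' @param path Path to a YAML file.
#' @return A [registry_schema()] object.
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variables)) abort("Schema file must declare `variables`.")
  v <- tibble(
    name = vapply(cfg$variables, `[[`, "", "name"),
    kind = vapply(cfg$variables, `[[`, "", "kind"),
    levels = lapply(cfg$variables, function(x) as.character(x$levels %||% character())),
    units = vapply(cfg$variables, function(x) x$units %||% NA_character_, "")
  )
  registry_schema(v, outcome = cfg$outcome %||% "outcome", strata = cfg$strata)
}

# Encoded-column metadata: one row per column after one-hot encoding.
encoded_columns <- function(schema) {
  rows <- purrr::pmap(schema, function(name, kind, levels, units) {
    if (kind == "categorical") {
      tibble(column = paste(name, levels, sep = "."),
             kind = "binary", source = name, level = levels)
    } else {
      tibble(column = name, kind = kind, source = name, level = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

# One-hot encode raw predictor columns according to the schema, with the
# error contract: unknown categorical level names column and level;
# non-numeric continuous cells name the row.
encode_predictors <- function(raw, schema) {
  out <- list()
  for (k in seq_len(nrow(schema))) {
    nm <- schema$name[k]; kind <- schema$kind[k]
    if (!nm %in% names(raw)) abort(sprintf("Column `%s` not found in data.", nm))
    x <- raw[[nm]]
    if (kind == "categorical") {
      lv <- schema$levels[[k]]
      x <- as.character(x)
      unknown <- setdiff(unique(x[!is.na(x)]), lv)
      if (length(unknown)) {
        abort(sprintf("Unknown level(s) in categorical column `%s`: %s",
                      nm, paste(unknown, collapse = ", ")))
      }
      for (l in lv) {
        ind <- as.numeric(x == l)
        ind[is.na(x)] <- NA_real_
        out[[paste(nm, l, sep = ".")]] <- ind
      }
    } else {
      if (is.character(x) || is.factor(x)) {
        xr <- as.character(x)
        num <- suppressWarnings(as.numeric(xr))
        bad <- which(!is.na(xr) & xr != "" & is.na(num))
        if (length(bad)) {
          abort(sprintf("Non-numeric value in %s column `%s` at row %d: \"%s\"",
                        kind, nm, bad[1], xr[bad[1]]))
        }
        num[!is.na(xr) & xr == ""] <- NA_real_
        x <- num
      }
      x <- as.numeric(x)
      if (kind == "binary") check_binary(x, nm)
      out[[nm]] <- x
    }
  }
  as_tibble(out)
}
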