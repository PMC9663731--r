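#' Median anchor and scale of every encoded column
#'
#' The anchor is the point at which all partial responses vanish: the
#' sample median for continuous columns (even n: mean of the central pair)
#' and the modal value for binary/indicator columns (an exact 50/50 tie
#' anchors at 0). The scale is the sample standard deviation of the
#' observed values. Anchors and scales use observed (non-missing) entries
#' only; constant columns are rejected because they cannot be standardized.
#'
#' @param data An encoded tibble (see [read_registry()], [as_registry()]).
#' @param outcome Name of the outcome column to exclude.
#' @return A tibble of class `prn_anchor` with columns `column`, `kind`,
#'   `anchor`, `scale`.
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3, 4), z = c(0, 0, 0, 1))
#' compute_anchor(d) # x anchored at 2.5, z at 0
#' @export
compute_anchor <- function(data, outcome = attr(data, "outcome") %||% "outcome") {
  sc <- table_schema(data, outcome)
  rows <- purrr::pmap(sc[, c("column", "kind")], function(column, kind) {
    x <- data[[column]]
    x <- x[!is.na(x)]
    if (!length(x)) abort(sprintf("Column `%s` has no observed values.", column))
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      abort(sprintf("Column `%s` is constant; remove it before anchoring.", column))
    }
    a <- if (kind == "binary") {
      p1 <- mean(x == 1)
      if (p1 > 0.5) 1 else 0  # exact tie anchors at 0
    } else {
      stats::median(x)
    }
    tibble(column = column, kind = kind, anchor = a, scale = s)
  })
  structure(dplyr::bind_rows(rows), class = c("prn_anchor", class(tibble())))
}

anchor_check <- function(data, anchor, outcome = attr(data, "outcome") %||% "outcome") {
  cols <- predictor_cols(data, outcome)
  if (!setequal(cols, anchor$column)) {
    abort("Anchor columns do not match the table's predictor columns.")
  }
  invisible(cols)
}

#' Median-anchored standardization
#'
#' Maps each predictor column to `(raw - anchor) / scale`, so a row sitting
#' exactly at the anchor maps to the zero vector and, downstream, makes no
#' contribution to any partial response. Missing entries stay missing; the
#' outcome column is untouched. The transformation is invertible via
#' [unstandardize()].
#'
#' @param data An encoded tibble.
#' @param anchor A [compute_anchor()] result for a compatible table.
#' @inheritParams compute_anchor
#' @return The standardized tibble, carrying the anchor in attribute
#'   `anchor`.
#' @export
standardize <- function(data, anchor,
                        outcome = attr(data, "outcome") %||% "outcome") {
  anchor_check(data, anchor, outcome)
  out <- data
  for (k in seq_len(nrow(anchor))) {
    nm <- anchor$column[k]
    out[[nm]] <- (data[[nm]] - anchor$anchor[k]) / anchor$scale[k]
  }
  attr(out, "anchor") <- anchor
  out
}

#' @rdname standardize
#' @export
unstandardize <- function(data, anchor = attr(data, "anchor"),
                          outcome = attr(data, "outcome") %||% "outcome") {
  if (is.null(anchor)) abort("No anchor supplied or attached to the table.")
  anchor_check(data, anchor, outcome)
  out <- data
  for (k in seq_len(nrow(anchor))) {
    nm <- anchor$column[k]
    out[[nm]] <- data[[nm]] * anchor$scale[k] + anchor$anchor[k]
  }
  attr(out, "anchor") <- NULL
  out
}

#' Anchor (zero) imputation of a standardized table
#'
#' Replaces every missing predictor entry of a standardized table with 0,
#' i.e. the column's median anchor on the raw scale. Because every partial
#' response vanishes at the anchor, imputed entries contribute nothing to
#' the model prediction. Observed entries are never changed.
#'
#' @param data A standardized tibble (see [standardize()]).
#' @inheritParams compute_anchor
#' @return The tibble with all predictor `NA`s set to 0.
#' @export
impute_zero <- function(data, outcome = attr(data, "outcome") %||% "outcome") {
  out <- data
  for (nm in predictor_cols(data, outcome)) {
    x <- out[[nm]]
    x[is.na(x)] <- 0
    out[[nm]] <- x
  }
  out
}
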