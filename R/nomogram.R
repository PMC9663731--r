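#' Export a nomogram table
#'
#' Tabulates, for every retained term, the mapping from a predictor value
#' (in raw units when an anchor is available) to its additive logit
#' contribution and the corresponding odds-ratio contribution
#' `exp(logit)`. Summing the logit columns of a patient's values and
#' adding the global intercept reproduces the model's log-odds; the anchor
#' value of any variable contributes an odds ratio of exactly 1. A
#' bivariate (continuous-by-indicator) term is exported as one curve per
#' indicator level.
#'
#' @param model A selected [prn_lasso][select_responses()] (e.g. the final
#'   PRN-Lasso from [prn_to_lasso()]).
#' @param anchor Optional [compute_anchor()] result used to report raw
#'   units; defaults to the anchor attached to the decomposition. Without
#'   one, values stay in standardized units.
#' @return A tibble of class `prn_nomogram` with columns `term`,
#'   `variable`, `value` (raw units), `level` (indicator level for
#'   bivariate terms), `logit` and `odds_ratio`; the model intercept is in
#'   attribute `intercept`.
#' @export
export_nomogram <- function(model, anchor = NULL) {
  if (is.null(model$selected)) abort("Run select_responses() first.")
  decomp <- model$decomp
  anchor <- anchor %||% decomp$anchor
  to_raw <- function(var, std) {
    if (is.null(anchor)) return(std)
    k <- match(var, anchor$column)
    std * anchor$scale[k] + anchor$anchor[k]
  }
  rows <- purrr::map_dfr(model$selected, function(nm) {
    r <- decomp$responses[[nm]]
    b <- unname(model$beta[nm])
    if (r$order == 1L) {
      lg <- b * as.numeric(r$values)
      tibble(term = nm, variable = r$vars[1],
             value = to_raw(r$vars[1], r$grids[[1]]),
             level = NA_real_, logit = lg, odds_ratio = exp(lg))
    } else {
      # continuous axis first; if both kinds equal, keep stored order
      flip <- r$kinds[1] == "binary" && r$kinds[2] != "binary"
      ci <- if (flip) 2L else 1L; bi <- if (flip) 1L else 2L
      purrr::map_dfr(seq_along(r$grids[[bi]]), function(l) {
        raw_level <- to_raw(r$vars[bi], r$grids[[bi]][l])
        vals <- if (bi == 2L) r$values[, l] else r$values[l, ]
        lg <- b * as.numeric(vals)
        tibble(term = nm, variable = r$vars[ci],
               value = to_raw(r$vars[ci], r$grids[[ci]]),
               level = raw_level, logit = lg, odds_ratio = exp(lg))
      })
    }
  })
  structure(rows, intercept = model$intercept,
            units = if (is.null(anchor)) "standardized" else "raw",
            class = c("prn_nomogram", class(tibble())))
}

#' Write a nomogram table to delimited text
#'
#' @param nomogram An [export_nomogram()] result.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_nomogram <- function(nomogram, path, delim = ",") {
  out <- as_tibble(nomogram)
  out$intercept <- attr(nomogram, "intercept")
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
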