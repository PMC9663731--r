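#' Stacked donor-based multiple imputation
#'
#' The registry imputation scheme used for model development: each missing
#' value is replaced `m` times by an observed value drawn uniformly (with
#' replacement) from the same column within the same stratum, and the `m`
#' completed copies are stacked row-wise into one table of `m * n` rows
#' (column `.imp` records the copy). No variance pooling is performed; the
#' stacked table is used directly as the derivation cohort so that random
#' fluctuations in the imputed slots counterweight each other.
#'
#' @param data An encoded tibble on the raw scale.
#' @param strata Name of a fully observed column defining the imputation
#'   strata (e.g. a transplant-era band). Defaults to the schema's strata
#'   column.
#' @param m Number of imputed copies (default 10).
#' @param seed Integer seed; the result is bit-identical across runs for a
#'   fixed seed.
#' @inheritParams compute_anchor
#' @return A tibble with `m * nrow(data)` rows and an `.imp` column.
#' @export
impute_donors <- function(data, strata = attr(data, "strata"), m = 10, seed = 1,
                          outcome = attr(data, "outcome") %||% "outcome") {
  if (is.null(strata) || !strata %in% names(data)) {
    abort("`strata` must name a column of `data`.")
  }
  if (anyNA(data[[strata]])) abort("The strata column must be fully observed.")
  cols <- setdiff(predictor_cols(data, outcome), strata)
  groups <- split(seq_len(nrow(data)), data[[strata]])
  # Donor pools: observed values per column within each stratum, validated
  # up front so the error names both the stratum and the column.
  pools <- lapply(groups, function(idx) {
    lapply(stats::setNames(cols, cols), function(nm) {
      v <- data[[nm]][idx]
      v[!is.na(v)]
    })
  })
  for (g in names(pools)) {
    for (nm in cols) {
      if (anyNA(data[[nm]][groups[[g]]]) && !length(pools[[g]][[nm]])) {
        abort(sprintf("Stratum `%s` has no observed donor values for column `%s`.",
                      g, nm))
      }
    }
  }
  withr::local_seed(as.integer(seed))
  copies <- lapply(seq_len(m), function(i) {
    out <- data
    for (g in names(groups)) {
      idx <- groups[[g]]
      for (nm in cols) {
        miss <- idx[is.na(data[[nm]][idx])]
        if (length(miss)) {
          pool <- pools[[g]][[nm]]
          out[[nm]][miss] <- pool[sample.int(length(pool), length(miss), replace = TRUE)]
        }
      }
    }
    out$.imp <- i
    out
  })
  out <- dplyr::bind_rows(copies)
  for (a in c("schema", "raw_schema", "outcome", "strata")) {
    attr(out, a) <- attr(data, a)
  }
  out
}
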