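#' Per-patient additive explanation
#'
#' Breaks a prediction into its additive pieces: one logit contribution per
#' retained partial response, plus the model intercept. The contributions
#' and the intercept sum exactly to the model's logit, which through the
#' sigmoid gives the predicted probability — the explanation *is* the
#' prediction. A patient sitting at the median anchor has every
#' contribution equal to zero.
#'
#' @param model A selected [prn_lasso][select_responses()] or a
#'   [prn_network].
#' @param data One or more standardized, imputed rows.
#' @param ... Unused.
#' @return A tibble of class `prn_explanation`: one row per input row,
#'   one column per term (logit units), plus `.intercept`, `.logit` and
#'   `.probability`.
#' @export
explain <- function(model, data, ...) UseMethod("explain")

#' @export
explain.prn_lasso <- function(model, data, ...) {
  if (is.null(model$selected)) abort("Run select_responses() first.")
  feats <- response_features(model$decomp, data, terms = model$selected)
  contrib <- if (length(model$selected)) {
    purrr::map2_dfc(feats[model$selected], model$beta[model$selected],
                    function(f, b) f * b)
  } else {
    tibble(.rows = nrow(feats))
  }
  new_explanation(contrib, model$intercept)
}

#' @export
explain.prn_network <- function(model, data, ...) {
  X <- model_matrix(model, data)
  contrib <- as_tibble(lapply(model$modules, function(m) module_output(m, X)))
  new_explanation(contrib, model$intercept)
}

new_explanation <- function(contrib, intercept) {
  terms <- names(contrib)
  out <- contrib
  out$.intercept <- intercept
  out$.logit <- rowSums(as.matrix(contrib)) + intercept
  out$.probability <- sigmoid(out$.logit)
  structure(out, terms = terms,
            class = c("prn_explanation", class(tibble())))
}

#' @method tidy prn_explanation
#' @export
tidy.prn_explanation <- function(x, ...) {
  terms <- attr(x, "terms")
  long <- tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x)[, terms, drop = FALSE], .row = dplyr::row_number()),
    -".row", names_to = "term", values_to = "contribution")
  long$odds_ratio <- exp(long$contribution)
  long
}

#' @export
print.prn_explanation <- function(x, ...) {
  cat(sprintf("<prn_explanation> %d row(s); intercept %.4f\n",
              nrow(x), x$.intercept[1]))
  print(as_tibble(x))
  invisible(x)
}
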