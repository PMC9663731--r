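# ggplot2 methods for the main result types.

#' @method autoplot prn_anova
#' @export
autoplot.prn_anova <- function(object, terms = NULL, ...) {
  td <- tidy(object)
  td <- td[td$order == 1L, , drop = FALSE]
  if (!is.null(terms)) td <- td[td$term %in% terms, , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x1, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "standardized value",
                  y = "contribution to log-odds",
                  title = "Univariate partial responses")
}

#' @method autoplot prn_explanation
#' @export
autoplot.prn_explanation <- function(object, row = 1, ...) {
  terms <- attr(object, "terms")
  d <- tibble(term = terms,
              contribution = as.numeric(as_tibble(object)[row, terms]))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$term, .data$contribution),
                                  y = .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "logit contribution",
                  title = sprintf("Additive explanation (row %d): p = %.3f",
                                  row, object$.probability[row]))
}

#' @method autoplot prn_nomogram
#' @export
autoplot.prn_nomogram <- function(object, ...) {
  d <- as_tibble(object)
  d$curve <- ifelse(is.na(d$level), d$term,
                    paste0(d$term, " = ", d$level))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$odds_ratio,
                                  colour = .data$curve)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "value", y = "odds-ratio contribution",
                  colour = NULL, title = "Nomogram")
}

#' Calibration plot data/figure
#'
#' Observed event rate against mean predicted probability per risk group,
#' with exact binomial intervals and the identity line.
#'
#' @param probs Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param groups Number of risk groups.
#' @return A ggplot object.
#' @export
plot_calibration <- function(probs, labels, groups = 10) {
  cal <- calibration_summary(probs, labels, groups)
  ggplot2::ggplot(cal$groups, ggplot2::aes(x = .data$mean_p, y = .data$obs_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "expected probability", y = "observed probability",
                  title = sprintf("Calibration: E/O %.2f, CITL %.3f",
                                  cal$eo_ratio, cal$citl))
}

#' @method autoplot prn_lasso
#' @export
autoplot.prn_lasso <- function(object, ...) {
  pt <- lasso_path_table(object)
  ggplot2::ggplot(pt, ggplot2::aes(x = log(.data$lambda), y = .data$estimate,
                                   colour = .data$term)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = log(object$lambda %||% NA_real_),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "log(lambda)", y = "coefficient",
                  title = "Lasso coefficient paths")
}
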