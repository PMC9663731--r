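#' Area under the ROC curve
#'
#' The probability that a randomly chosen event case is scored above a
#' randomly chosen non-event case, with ties counted one half (mid-rank
#' convention).
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param labels 0/1 outcome labels.
#' @return The AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auroc <- function(scores, labels) {
  check_binary(labels, "labels")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp),
       m = m, n = n)
}

#' DeLong confidence interval for an AUROC
#'
#' Normal-approximation interval from the nonparametric structural-
#' component variance of DeLong, truncated to `[0, 1]`.
#'
#' @inheritParams auroc
#' @param level Confidence level (default 0.95).
#' @return A named numeric vector `c(lo, hi)` with attributes `auc` and
#'   `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  check_binary(labels, "labels")
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    abort("At least two observations per class are required.")
  }
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  if (!is.finite(v) || v <= 0) {
    abort("Degenerate DeLong variance (all scores tied within a class).")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(c(lo = ci[1], hi = ci[2]), auc = dc$auc, se = sqrt(v))
}

#' DeLong paired comparison of two correlated AUROCs
#'
#' Two-sided test of equal AUROC for two models scoring the same rows,
#' using the DeLong covariance of the paired structural components.
#'
#' @param scores_a,scores_b Scores of the two models on the same rows.
#' @inheritParams auroc
#' @return An `htest`-like list with `statistic`, `p.value`, `estimate`
#'   (the two AUROCs) and `difference`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_binary(labels, "labels")
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    warn("Identical score vectors; p-value is 1 by convention.")
    return(structure(list(statistic = c(z = 0), p.value = 1,
                          estimate = c(auc_a = auroc(scores_a, labels),
                                       auc_b = auroc(scores_b, labels)),
                          difference = 0,
                          method = "DeLong test for two correlated ROC curves"),
                     class = "htest"))
  }
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  diff <- da$auc - db$auc
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v) || v <= 0) {
    abort("Degenerate DeLong variance for the paired comparison.")
  }
  z <- diff / sqrt(v)
  structure(list(statistic = c(z = z), p.value = 2 * stats::pnorm(-abs(z)),
                 estimate = c(auc_a = da$auc, auc_b = db$auc),
                 difference = diff,
                 method = "DeLong test for two correlated ROC curves"),
            class = "htest")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups rows into deciles of risk (equal-count groups by sorted
#' predicted probability, with tied probabilities kept in one group) and
#' compares observed with expected event counts in both outcome classes:
#' `sum over groups and classes of (obs - exp)^2 / exp`, referred to a
#' chi-square with `groups - 2` degrees of freedom.
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels 0/1 outcomes.
#' @param groups Number of risk groups (default 10).
#' @return A list with `statistic`, `df`, `p.value` and the per-group
#'   `table` (a tibble).
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10) {
  check_binary(labels, "labels")
  if (groups < 3) abort("`groups` must be at least 3.")
  if (any(probs <= 0 | probs >= 1)) abort("`probs` must lie strictly in (0, 1).")
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = groups + 1), type = 2))
  g <- cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- dplyr::summarise(
    dplyr::group_by(tibble(g = g, p = probs, y = labels), .data$g),
    n = dplyr::n(), obs = sum(.data$y), exp = sum(.data$p),
    mean_p = mean(.data$p), .groups = "drop")
  if (any(tab$exp < 1e-12) || any((tab$n - tab$exp) < 1e-12)) {
    abort("A group has an expected count of zero; use fewer groups.")
  }
  stat <- sum((tab$obs - tab$exp)^2 / tab$exp +
                ((tab$n - tab$obs) - (tab$n - tab$exp))^2 / (tab$n - tab$exp))
  df <- nrow(tab) - 2
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Calibration summary: E/O ratio and calibration-in-the-large
#'
#' The expected/observed event ratio (`sum(probs) / sum(labels)`), the
#' calibration-in-the-large (intercept of a logistic recalibration of the
#' outcome on the model's logit with slope fixed at 1, per TRIPOD), the
#' free recalibration slope for reference, and per-group observed and
#' expected probabilities with exact binomial intervals for plotting.
#'
#' @inheritParams hosmer_lemeshow
#' @return A list with `eo_ratio`, `citl`, `slope` and a `groups` tibble
#'   (`mean_p`, `obs_rate`, `lo`, `hi`, `n`).
#' @export
calibration_summary <- function(probs, labels, groups = 10) {
  check_binary(labels, "labels")
  if (sum(labels) == 0) abort("No observed events; E/O ratio is undefined.")
  lp <- logit(pmin(pmax(probs, 1e-12), 1 - 1e-12))
  citl <- unname(coef(stats::glm(labels ~ 1 + offset(lp), family = stats::binomial())))
  slope <- unname(coef(stats::glm(labels ~ lp, family = stats::binomial()))[2])
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = groups + 1), type = 2))
  g <- cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  gt <- dplyr::summarise(
    dplyr::group_by(tibble(g = g, p = probs, y = labels), .data$g),
    n = dplyr::n(), mean_p = mean(.data$p), obs = sum(.data$y), .groups = "drop")
  ci <- purrr::map2_dfr(gt$obs, gt$n, function(x, n) {
    b <- stats::binom.test(x, n)$conf.int
    tibble(lo = b[1], hi = b[2])
  })
  list(eo_ratio = sum(probs) / sum(labels), citl = citl, slope = slope,
       groups = dplyr::bind_cols(gt[, c("g", "n", "mean_p")],
                                 obs_rate = gt$obs / gt$n, ci))
}

#' Discrimination and calibration report for scored models
#'
#' One row per score column: AUROC with its DeLong interval, the DeLong
#' p-value against the first (reference) model, the Hosmer-Lemeshow
#' statistic, and the calibration summary.
#'
#' @param data A tibble holding the label column and one column of
#'   predicted probabilities per model.
#' @param score_cols Character vector of score column names; the first is
#'   the reference for paired comparisons.
#' @param label Name of the 0/1 outcome column.
#' @param groups Risk groups for calibration statistics.
#' @param level Confidence level for AUROC intervals.
#' @return A tibble with one row per model.
#' @export
evaluate_scores <- function(data, score_cols, label = "outcome",
                            groups = 10, level = 0.95) {
  y <- data[[label]]
  purrr::map_dfr(score_cols, function(nm) {
    p <- data[[nm]]
    ci <- tryCatch(delong_ci(p, y, level), error = function(e) {
      structure(c(lo = NA_real_, hi = NA_real_), auc = auroc(p, y),
                se = NA_real_)
    })
    hl <- tryCatch(hosmer_lemeshow(p, y, groups), error = function(e) {
      list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_)
    })
    cal <- calibration_summary(p, y, groups)
    dl_p <- if (nm == score_cols[1]) NA_real_ else {
      tryCatch(delong_test(data[[score_cols[1]]], p, y)$p.value,
               warning = function(w) 1, error = function(e) NA_real_)
    }
    tibble(model = nm, n = length(y), auroc = attr(ci, "auc"),
           ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
           delong_p_vs_ref = dl_p,
           hl_stat = hl$statistic, hl_df = hl$df, hl_p = hl$p.value,
           eo_ratio = cal$eo_ratio, citl = cal$citl,
           cal_slope = cal$slope)
  })
}
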