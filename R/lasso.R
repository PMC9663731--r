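#' Partial responses as model features
#'
#' Evaluates every retained partial response on every row of a fully
#' imputed standardized table, through the source model directly (never by
#' interpolation), giving the design matrix of the response-level
#' generalized additive model. A row at the anchor yields an all-zero row.
#'
#' @param decomp A [decompose_logit()] result.
#' @param data Standardized, imputed rows.
#' @param terms Optional character vector restricting to a subset of
#'   response names.
#' @return A tibble with one column per response, in decomposition order,
#'   plus attribute `decomp`.
#' @export
response_features <- function(decomp, data, terms = NULL) {
  if (!is.null(terms)) {
    missing_terms <- setdiff(terms, names(decomp$responses))
    if (length(missing_terms)) {
      abort(sprintf("Unknown response term(s): %s", paste(missing_terms, collapse = ", ")))
    }
    decomp$responses <- decomp$responses[names(decomp$responses) %in% terms]
  }
  vals <- response_values_direct(decomp$model, decomp, data)
  out <- if (length(vals)) as_tibble(vals) else tibble(.rows = nrow(data))
  attr(out, "decomp") <- decomp
  out
}

#' L1-penalized logistic regression over partial responses
#'
#' Fits the lasso path of a logistic regression whose inputs are the
#' partial-response features, with k-fold cross-validated deviance along a
#' decreasing lambda grid (100 log-spaced values down to `1e-4` of the
#' smallest all-zero lambda). Features are not re-standardized: they
#' already live on the logit scale, so equal penalization there is the
#' interpretable default (set `standardize = TRUE` for sensitivity
#' analysis). Fold assignment is seeded, so the path and the selection are
#' reproducible.
#'
#' @param features Tibble or matrix of response features (see
#'   [response_features()]).
#' @param outcome 0/1 outcome vector.
#' @param nfolds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param standardize Re-standardize features before penalization?
#'   Default `FALSE`.
#' @param nlambda,lambda.min.ratio Path grid controls.
#' @return An object of class `prn_lasso` holding the glmnet path, the CV
#'   curve, and (after [select_responses()]) the chosen model.
#' @export
fit_response_lasso <- function(features, outcome, nfolds = 10, seed = 1,
                               standardize = FALSE, nlambda = 100,
                               lambda.min.ratio = 1e-4) {
  X <- if (is.matrix(features)) features else as_numeric_matrix(features, names(features))
  y <- outcome
  check_binary(y, "outcome")
  if (length(unique(y)) < 2L) abort("Both outcome classes must be present.")
  if (nfolds < 2L) abort("`nfolds` must be at least 2.")
  withr::local_seed(as.integer(seed))
  foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  if (ncol(X) == 0L) {
    # no candidate responses at all: the only model is the prevalence
    return(structure(list(fit = NULL, cv = NULL, foldid = foldid,
                          features = character(), entry_index = integer(),
                          decomp = attr(features, "decomp"), seed = seed,
                          standardize = standardize,
                          null_intercept = qlogis(mean(y))),
                     class = "prn_lasso"))
  }
  # glmnet requires >= 2 columns; a single-response candidate set is padded
  # with an all-zero dummy whose coefficient is identically zero
  padded <- ncol(X) == 1L
  if (padded) X <- cbind(X, .prnpad = 0)
  fit <- glmnet::glmnet(X, y, family = "binomial", standardize = standardize,
                        nlambda = nlambda, lambda.min.ratio = lambda.min.ratio)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", standardize = standardize,
                          lambda = fit$lambda, foldid = foldid,
                          type.measure = "deviance")
  B <- as.matrix(fit$beta)
  entry <- apply(B != 0, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  feature_names <- setdiff(colnames(X), ".prnpad")
  entry <- entry[feature_names]
  structure(list(fit = fit, cv = cv, foldid = foldid,
                 features = feature_names, entry_index = entry,
                 decomp = attr(features, "decomp"),
                 seed = seed, standardize = standardize),
            class = "prn_lasso")
}

#' Choose the final model on the lasso path
#'
#' Picks the penalty by the cross-validated minimum-deviance rule
#' (`"min_cv"`, default) or the one-standard-error rule (`"one_se"`), and
#' records the order in which responses entered the path (which terms
#' survive the strongest regularization).
#'
#' @param path A [fit_response_lasso()] result.
#' @param rule `"min_cv"` or `"one_se"`.
#' @return The same object with elements `lambda`, `rule`, `intercept`,
#'   `beta` (named, selected terms only) and `selected` filled in.
#' @export
select_responses <- function(path, rule = c("min_cv", "one_se")) {
  rule <- match.arg(rule)
  if (is.null(path$fit)) {
    out <- path
    out$rule <- rule; out$lambda <- Inf
    out$intercept <- path$null_intercept
    out$beta <- numeric(); out$selected <- character()
    return(out)
  }
  lambda <- if (rule == "min_cv") path$cv$lambda.min else path$cv$lambda.1se
  cf <- coef(path$fit, s = lambda, exact = FALSE)
  beta <- drop(as.matrix(cf))
  intercept <- beta[1]
  beta <- beta[-1]
  selected <- names(beta)[beta != 0]
  out <- path
  out$rule <- rule
  out$lambda <- lambda
  out$intercept <- unname(intercept)
  out$beta <- beta[selected]
  out$selected <- selected
  out
}

#' @export
predict.prn_lasso <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(object$selected)) abort("Run select_responses() first.")
  X <- if (is.matrix(newdata)) newdata else as_numeric_matrix(newdata, names(newdata))
  missing_cols <- setdiff(object$selected, colnames(X))
  if (length(missing_cols)) {
    abort(sprintf("Missing feature column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  eta <- object$intercept +
    drop(X[, object$selected, drop = FALSE] %*% object$beta)
  if (type == "response") sigmoid(eta) else eta
}

#' @export
print.prn_lasso <- function(x, ...) {
  if (is.null(x$selected)) {
    cat(sprintf("<prn_lasso path> %d features, %d lambda values\n",
                length(x$features), length(x$fit$lambda)))
  } else {
    cat(sprintf("<prn_lasso> rule %s, lambda %.5f; %d of %d responses selected\n",
                x$rule, x$lambda, length(x$selected), length(x$features)))
  }
  invisible(x)
}

#' @method tidy prn_lasso
#' @export
tidy.prn_lasso <- function(x, ...) {
  if (is.null(x$selected)) abort("Run select_responses() first.")
  tibble(term = x$selected, estimate = unname(x$beta),
         entry_index = x$entry_index[x$selected])
}

#' @method glance prn_lasso
#' @export
glance.prn_lasso <- function(x, ...) {
  tibble(rule = x$rule %||% NA_character_, lambda = x$lambda %||% NA_real_,
         n_selected = length(x$selected %||% character()),
         n_candidates = length(x$features),
         cv_deviance_min = min(x$cv$cvm), nfolds = max(x$foldid))
}

#' Full lasso path as a table
#'
#' One row per (lambda, term) with the coefficient, plus the CV deviance
#' per lambda, mirroring the usual path diagnostics plots.
#'
#' @param path A [fit_response_lasso()] result.
#' @return A tibble with columns `lambda`, `cv_deviance`, `cv_se`, `term`,
#'   `estimate`, `n_nonzero`.
#' @export
lasso_path_table <- function(path) {
  B <- as.matrix(path$fit$beta)
  B <- B[rownames(B) != ".prnpad", , drop = FALSE]
  lam <- path$fit$lambda
  cvm <- path$cv$cvm[match(lam, path$cv$lambda)]
  cvsd <- path$cv$cvsd[match(lam, path$cv$lambda)]
  purrr::map_dfr(seq_along(lam), function(s) {
    tibble(lambda = lam[s], cv_deviance = cvm[s], cv_se = cvsd[s],
           term = rownames(B), estimate = B[, s],
           n_nonzero = sum(B[, s] != 0))
  })
}
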