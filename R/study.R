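#' One end-to-end PRN study on synthetic data, in memory
#'
#' Convenience wrapper running the whole method once without touching the
#' file system: simulate a training and a held-out table under a ground
#' truth spec, anchor and standardize, fit the base MLP, decompose, select
#' by lasso, build and retrain the PRN, run the second selection pass, and
#' score both the base model and the final PRN-Lasso on the held-out rows.
#' Used by the recovery and performance-preservation checks and by the
#' reproduction script.
#'
#' @param seed Integer seed; all stage seeds derive from it.
#' @param n_train,n_test Rows in the training and held-out tables.
#' @param spec_args Extra arguments for [registry_spec()] (e.g.
#'   `missing_rate`).
#' @param hidden,l2 Base-MLP architecture controls.
#' @param nfolds,rule Lasso cross-validation controls.
#' @param n_grid Decomposition grid resolution.
#' @param max_epochs Cap on base-MLP training epochs.
#' @return A list with the spec, anchor, fitted objects (`mlp`, `gam`,
#'   `prn`, `final`), the held-out score tibble and AUROCs.
#' @export
prn_study <- function(seed = 1, n_train = 20000, n_test = 5000,
                      spec_args = list(), hidden = c(4, 8, 16), l2 = 1e-3,
                      nfolds = 10, rule = "min_cv", n_grid = 101,
                      max_epochs = 500) {
  spec_tr <- do.call(registry_spec,
                     utils::modifyList(list(n = n_train,
                                            seed = derive_seed(seed, "train")),
                                       spec_args))
  spec_te <- do.call(registry_spec,
                     utils::modifyList(list(n = n_test,
                                            seed = derive_seed(seed, "test")),
                                       spec_args))
  train <- simulate_registry(spec_tr)
  test <- simulate_registry(spec_te)
  anchor <- compute_anchor(train)
  train_s <- impute_zero(standardize(train, anchor))
  test_s <- impute_zero(standardize(test, anchor))

  mlp <- fit_mlp(train_s, hidden = hidden, l2 = l2,
                 seed = derive_seed(seed, "fit"), max_epochs = max_epochs)
  decomp <- decompose_logit(mlp, train_s, max_order = 2, n_grid = n_grid)
  feats <- response_features(decomp, train_s)
  path <- fit_response_lasso(feats, train_s$outcome, nfolds = nfolds,
                             seed = derive_seed(seed, "select"))
  gam <- select_responses(path, rule = rule)
  prn0 <- build_prn(mlp, gam)
  prn <- retrain_prn(prn0, train_s, seed = derive_seed(seed, "refine"))
  final <- prn_to_lasso(prn, train_s, nfolds = nfolds,
                        seed = derive_seed(seed, "refine_select"),
                        rule = rule, n_grid = n_grid)
  scored <- tibble(
    outcome = test_s$outcome,
    mlp = predict(mlp, test_s, type = "response"),
    prn_lasso = predict(final, response_features(final$decomp, test_s,
                                                 terms = final$selected)))
  list(spec = spec_tr, anchor = anchor, train = train_s, test = test_s,
       mlp = mlp, decomposition = decomp, gam = gam, prn = prn,
       final = final, scored = scored,
       auroc_mlp = auroc(scored$mlp, scored$outcome),
       auroc_prn = auroc(scored$prn_lasso, scored$outcome))
}

#' Compare recovered responses with the generating truth
#'
#' Evaluates each truly active anchored component and the corresponding
#' recovered response of a final model over the central data mass of its
#' variable(s), and reports the root-mean-square discrepancy in logit
#' units.
#'
#' @param study A [prn_study()] result.
#' @param mass Central data-mass fraction over which to compare (default
#'   0.9).
#' @param min_amplitude Components whose anchored truth never exceeds this
#'   many logit units are treated as null (this filters out the vanishing
#'   slice of the interaction at the anchored flag level).
#' @return A tibble with columns `term`, `active`, `selected`, `rmse`.
#' @export
recovery_rmse <- function(study, mass = 0.9, min_amplitude = 0.05) {
  spec <- study$spec
  anchor <- study$anchor
  truth <- true_partial_responses(spec, anchor)
  final <- study$final
  a <- stats::setNames(anchor$anchor, anchor$column)
  s <- stats::setNames(anchor$scale, anchor$column)
  train_raw <- unstandardize(study$train, anchor)
  lo <- (1 - mass) / 2; hi <- 1 - lo

  active <- names(truth)[vapply(truth, function(tr) {
    max(abs(tr$values)) > min_amplitude
  }, TRUE)]
  purrr::map_dfr(active, function(nm) {
    tr <- truth[[nm]]
    sel <- nm %in% final$selected ||
      (tr$order == 2L && paste(rev(tr$vars), collapse = ":") %in% final$selected)
    model_term <- if (nm %in% final$selected) nm else
      paste(rev(tr$vars), collapse = ":")
    if (tr$order == 1L) {
      x <- train_raw[[tr$vars]]
      if (length(unique(x[!is.na(x)])) <= 2) {
        grid_raw <- sort(unique(x[!is.na(x)]))
      } else {
        q <- stats::quantile(x, c(lo, hi), na.rm = TRUE)
        grid_raw <- seq(q[1], q[2], length.out = 200)
      }
      true_vals <- tr$fun(grid_raw)
      est <- if (sel) {
        r <- final$decomp$responses[[model_term]]
        b <- unname(final$beta[model_term])
        b * evaluate_response(r, (grid_raw - a[[tr$vars]]) / s[[tr$vars]])
      } else rep(0, length(grid_raw))
      tibble(term = nm, active = TRUE, selected = sel,
             rmse = sqrt(mean((est - true_vals)^2)))
    } else {
      xv <- tr$vars[1]; zv <- tr$vars[2]
      q <- stats::quantile(train_raw[[xv]], c(lo, hi), na.rm = TRUE)
      grid_raw <- seq(q[1], q[2], length.out = 200)
      zlv <- sort(unique(train_raw[[zv]][!is.na(train_raw[[zv]])]))
      pts <- expand.grid(x = grid_raw, z = zlv)
      true_vals <- tr$fun(pts$x, pts$z)
      est <- if (sel) {
        r <- final$decomp$responses[[model_term]]
        b <- unname(final$beta[model_term])
        xs <- (pts$x - a[[xv]]) / s[[xv]]
        zs <- (pts$z - a[[zv]]) / s[[zv]]
        vals <- if (identical(r$vars[1], xv)) cbind(xs, zs) else cbind(zs, xs)
        b * evaluate_response(r, vals)
      } else rep(0, nrow(pts))
      tibble(term = nm, active = TRUE, selected = sel,
             rmse = sqrt(mean((est - true_vals)^2)))
    }
  })
}
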