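# Shared fixtures: all built in code, no files.

# Wrap a plain matrix as a standardized table with an outcome column.
std_tbl <- function(X, y = NULL) {
  nms <- colnames(X)
  if (is.null(nms)) nms <- rep("", ncol(X))
  blank <- !nzchar(nms)
  nms[blank] <- paste0("x", seq_len(ncol(X)))[blank]
  colnames(X) <- nms
  d <- tibble::as_tibble(as.data.frame(X))
  if (!is.null(y)) d$outcome <- y
  attr(d, "outcome") <- "outcome"
  d
}

`%||%` <- rlang::`%||%`

# A random single-hidden-layer network with d inputs, as a prn_mlp object.
random_mlp <- function(d, h = 5, seed = 1) {
  withr::with_seed(seed, {
    structure(list(W1 = matrix(rnorm(d * h), d, h), b1 = rnorm(h),
                   w2 = rnorm(h), b2 = rnorm(1), hidden = h,
                   columns = paste0("x", seq_len(d)), seed = seed,
                   l2 = 0, history = 0), class = "prn_mlp")
  })
}

# A small intercept-only generating spec (all effects null).
null_spec <- function(n, seed, intercept = -2) {
  v <- registry_variables()
  v$amplitude <- 0
  v$effect <- "none"
  registry_spec(n = n, seed = seed, intercept = intercept,
                variables = v, interaction = NULL)
}

# A compact active spec used where the full default preset is too heavy:
# same shapes, fewer columns.
small_spec <- function(n, seed, missing_rate = 0) {
  v <- registry_variables()
  v <- v[v$name %in% c("recipient_age", "donor_age", "ischemic_time", "icm",
                       "female"), ]
  registry_spec(n = n, seed = seed, missing_rate = missing_rate, variables = v)
}

# Fit a tiny end-to-end first pass (MLP -> decompose -> lasso) quickly.
quick_first_pass <- function(n = 1500, seed = 7, hidden = 4, nfolds = 3) {
  spec <- small_spec(n, seed)
  d <- simulate_registry(spec)
  anchor <- compute_anchor(d)
  ds <- impute_zero(standardize(d, anchor))
  mlp <- fit_mlp(ds, hidden = hidden, seed = seed, max_epochs = 150)
  decomp <- decompose_logit(mlp, ds)
  feats <- response_features(decomp, ds)
  gam <- select_responses(fit_response_lasso(feats, ds$outcome,
                                             nfolds = nfolds, seed = seed))
  list(spec = spec, data = ds, anchor = anchor, mlp = mlp, decomp = decomp,
       feats = feats, gam = gam)
}
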