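test_that("the PRN reproduces the lasso-GAM exactly at initialization", {
  fp <- quick_first_pass(n = 1200, seed = 17)
  prn <- build_prn(fp$mlp, fp$gam)
  expect_equal(length(prn$modules), length(fp$gam$selected))

  withr::local_seed(3)
  X <- matrix(rnorm(1000 * length(fp$mlp$columns)), 1000)
  colnames(X) <- fp$mlp$columns
  gam_logit <- predict(fp$gam,
                       response_features(fp$gam$decomp, std_tbl(X),
                                         terms = fp$gam$selected),
                       type = "link")
  expect_lt(max(abs(predict_logit(prn, X) - gam_logit)), 1e-8)

  # an empty selected set leaves only the intercept
  gam0 <- fp$gam
  gam0$selected <- character(); gam0$beta <- numeric()
  prn0 <- build_prn(fp$mlp, gam0)
  expect_equal(predict_logit(prn0, X[1:5, ]), rep(gam0$intercept, 5))
})

test_that("modules are blind to non-member variables, structurally", {
  fp <- quick_first_pass(n = 1200, seed = 17)
  prn <- build_prn(fp$mlp, fp$gam)
  withr::local_seed(4)
  X <- matrix(rnorm(50 * length(prn$columns)), 50)
  for (mod in prn$modules) {
    X2 <- X
    others <- setdiff(seq_len(ncol(X)), mod$idx)
    X2[, others] <- X2[, others] + matrix(rnorm(50 * length(others), 0, 10),
                                          50)
    expect_identical(prnet:::module_output(mod, X),
                     prnet:::module_output(mod, X2))
  }
})

test_that("modules stay exactly zero at the anchor before and after retraining", {
  fp <- quick_first_pass(n = 1200, seed = 19)
  prn <- build_prn(fp$mlp, fp$gam)
  prn_t <- retrain_prn(prn, fp$data, seed = 5, epochs = 60)
  zero <- matrix(0, 1, length(prn$columns))
  for (m in c(prn$modules, prn_t$modules)) {
    expect_identical(prnet:::module_output(m, zero), 0)
  }
  # slice-zero for a bivariate module, post retraining
  biv <- Filter(function(m) m$order == 2L, prn_t$modules)
  if (length(biv)) {
    m2 <- biv[[1]]
    Z <- matrix(0, 7, length(prn$columns))
    Z[, m2$idx[1]] <- seq(-2, 2, length.out = 7)
    expect_identical(prnet:::module_output(m2, Z), rep(0, 7))
  }
})

test_that("retraining descends and zero epochs is the identity", {
  fp <- quick_first_pass(n = 1500, seed = 23)
  prn <- build_prn(fp$mlp, fp$gam)
  expect_identical(retrain_prn(prn, fp$data, epochs = 0), prn)

  prn_t <- retrain_prn(prn, fp$data, seed = 6, epochs = 100)
  ck <- prn_t$meta$checkpoints
  expect_true(all(diff(ck) < 0))  # checkpoint losses strictly improve
  expect_true(isTRUE(prn_t$meta$retrained))
  # the retrained network should not be worse than the initialization on
  # its own validation objective
  expect_lte(prn_t$meta$val_loss, ck[1])
})

test_that("retraining repairs a corrupted initialization", {
  fp <- quick_first_pass(n = 4000, seed = 29)
  spec_te <- small_spec(3000, seed = 31)
  te <- impute_zero(standardize(simulate_registry(spec_te), fp$anchor))
  prn <- build_prn(fp$mlp, fp$gam)
  good <- retrain_prn(prn, fp$data, seed = 7)

  bad0 <- prn
  bad0$modules[[1]]$scale <- bad0$modules[[1]]$scale * 0.5
  bad <- retrain_prn(bad0, fp$data, seed = 7)

  ll <- function(m) prnet:::log_loss(predict_logit(m, te), te$outcome)
  expect_lt(ll(bad), ll(good) * 1.01)
})

test_that("the second pass recovers module responses and prunes only", {
  fp <- quick_first_pass(n = 2500, seed = 37)
  prn <- retrain_prn(build_prn(fp$mlp, fp$gam), fp$data, seed = 8, epochs = 80)
  fin <- prn_to_lasso(prn, fp$data, nfolds = 3, seed = 9)

  # candidate set is exactly the module set
  expect_setequal(names(fin$decomp$responses), names(prn$modules))
  expect_true(all(fin$selected %in% names(prn$modules)))

  # the anchored decomposition of the additive network recovers each
  # module's own function: cross-check the module fast path against the
  # generic anchored cuts of an opaque wrapper around the same network
  bb <- as_blackbox(function(X) predict_logit(prn, X), prn$columns)
  dc_generic <- decompose_logit(bb, fp$data,
                                terms = names(prn$modules))
  f_fast <- response_features(fin$decomp, fp$data[1:200, ])
  f_slow <- response_features(dc_generic, fp$data[1:200, ])
  for (nm in names(f_fast)) {
    expect_equal(f_fast[[nm]], f_slow[[nm]], tolerance = 1e-10)
  }

  # a single-module network yields a single candidate
  gam1 <- fp$gam
  keep <- fp$gam$selected[1]
  gam1$selected <- keep; gam1$beta <- fp$gam$beta[keep]
  prn1 <- build_prn(fp$mlp, gam1)
  fin1 <- prn_to_lasso(prn1, fp$data, nfolds = 3, seed = 10)
  expect_identical(names(fin1$decomp$responses), keep)
})

test_that("explanations add up exactly and vanish at the anchor", {
  fp <- quick_first_pass(n = 1500, seed = 41)
  prn <- retrain_prn(build_prn(fp$mlp, fp$gam), fp$data, seed = 11, epochs = 50)
  rows <- fp$data[1:20, ]
  ex <- explain(prn, rows)
  terms <- attr(ex, "terms")
  expect_setequal(terms, names(prn$modules))
  recon <- rowSums(as.matrix(tibble::as_tibble(ex)[, terms])) + ex$.intercept
  expect_lt(max(abs(recon - ex$.logit)), 1e-10)
  expect_equal(ex$.probability, plogis(ex$.logit))
  expect_equal(ex$.logit, predict_logit(prn, rows))

  anchor_row <- rows[1, ]
  for (nm in setdiff(names(anchor_row), "outcome")) anchor_row[[nm]] <- 0
  ex0 <- explain(prn, anchor_row)
  expect_equal(max(abs(as.numeric(tibble::as_tibble(ex0)[, terms]))), 0)
  expect_equal(ex0$.probability, plogis(prn$intercept))

  # explanations of the final lasso stage agree with its predictions
  fin <- prn_to_lasso(prn, fp$data, nfolds = 3, seed = 12)
  exf <- explain(fin, rows)
  pf <- predict(fin, response_features(fin$decomp, rows, terms = fin$selected))
  expect_equal(exf$.probability, pf)
})

test_that("the nomogram tabulates odds-ratio contributions in raw units", {
  fp <- quick_first_pass(n = 1500, seed = 43)
  prn <- retrain_prn(build_prn(fp$mlp, fp$gam), fp$data, seed = 13, epochs = 40)
  fin <- prn_to_lasso(prn, fp$data, nfolds = 3, seed = 14)
  nomo <- export_nomogram(fin, anchor = fp$anchor)

  expect_setequal(unique(nomo$term), fin$selected)
  expect_equal(nomo$odds_ratio, exp(nomo$logit))
  expect_equal(attr(nomo, "intercept"), fin$intercept)

  # the anchor value contributes an odds ratio of exactly 1
  for (tm in unique(nomo$term[is.na(nomo$level)])) {
    sub <- nomo[nomo$term == tm & is.na(nomo$level), ]
    av <- fp$anchor$anchor[fp$anchor$column == sub$variable[1]]
    at_anchor <- sub$odds_ratio[which.min(abs(sub$value - av))]
    expect_equal(at_anchor, 1)
  }

  # a bivariate term is exported as one curve per indicator level
  biv <- fin$selected[grepl(":", fin$selected)]
  if (length(biv)) {
    sub <- nomo[nomo$term == biv[1], ]
    expect_equal(length(unique(sub$level)), 2)
  }

  f <- withr::local_tempfile(fileext = ".csv")
  write_nomogram(nomo, f)
  expect_true(file.exists(f))
})

test_that("a serialized network reloads with bit-identical predictions", {
  fp <- quick_first_pass(n = 1200, seed = 47)
  prn <- retrain_prn(build_prn(fp$mlp, fp$gam), fp$data, seed = 15, epochs = 30)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(prn, f)
  prn2 <- read_model(f)
  X <- matrix(rnorm(40 * length(prn$columns)), 40)
  expect_identical(predict_logit(prn, X), predict_logit(prn2, X))
})
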