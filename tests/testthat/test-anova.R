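# Helper: decompose a closed-form black box over a given data table.
bb_decomp <- function(fun, data, ...) {
  decompose_logit(as_blackbox(fun, setdiff(names(data), "outcome")), data, ...)
}

test_that("simple closed-form surfaces decompose to their addends", {
  withr::local_seed(10)
  d <- std_tbl(cbind(x1 = rnorm(200), x2 = rnorm(200)))
  d$x1 <- d$x1 - median(d$x1)  # anchor the cut at zero exactly
  d$x2 <- d$x2 - median(d$x2)

  # constant surface: all responses identically zero
  dc0 <- bb_decomp(function(X) rep(1.7, nrow(X)), d)
  expect_true(all(vapply(dc0$responses, function(r) max(abs(r$values)), 0) == 0))
  expect_equal(dc0$intercept, 1.7)

  # additive identity g = x1: f1(t) = t, everything else zero
  dc1 <- bb_decomp(function(X) X[, 1], d)
  expect_equal(dc1$responses$x1$values, dc1$responses$x1$grids[[1]])
  expect_equal(max(abs(dc1$responses$x2$values)), 0)
  expect_equal(max(abs(dc1$responses[["x1:x2"]]$values)), 0)

  # g = x1^2 + x2 with zero anchor: f1 = t^2, f2 = t
  dc2 <- bb_decomp(function(X) X[, 1]^2 + X[, 2], d)
  expect_equal(dc2$responses$x1$values, dc2$responses$x1$grids[[1]]^2)
  expect_equal(dc2$responses$x2$values, dc2$responses$x2$grids[[1]])

  # pure interaction g = x1 * x2: mains vanish, f12(s, t) = s * t
  dc3 <- bb_decomp(function(X) X[, 1] * X[, 2], d)
  expect_equal(max(abs(dc3$responses$x1$values)), 0)
  expect_equal(max(abs(dc3$responses$x2$values)), 0)
  r12 <- dc3$responses[["x1:x2"]]
  expect_equal(r12$values, outer(r12$grids[[1]], r12$grids[[2]]),
               tolerance = 1e-12)
})

test_that("the decomposition enumerates d univariate and choose(d,2) pairs", {
  withr::local_seed(11)
  d <- std_tbl(matrix(rnorm(80), 20, 4))
  dc <- decompose_logit(random_mlp(4), d, max_order = 2)
  orders <- vapply(dc$responses, function(r) r$order, 1L)
  expect_equal(sum(orders == 1), 4)
  expect_equal(sum(orders == 2), 6)
  dc1 <- decompose_logit(random_mlp(4), d, max_order = 1)
  expect_equal(length(dc1$responses), 4)
  # cap on pairs keeps the most variable ones
  dcc <- decompose_logit(random_mlp(4), d, max_order = 2, max_pairs = 2)
  expect_equal(sum(vapply(dcc$responses, function(r) r$order, 1L) == 2), 2)
  # terms restriction
  dct <- decompose_logit(random_mlp(4), d, terms = c("x2", "x3:x1"))
  expect_setequal(names(dct$responses), c("x2", "x1:x3"))
  expect_error(decompose_logit(random_mlp(4), d, max_order = 3), "max_order")
})

test_that("anchored-zero and slice-zero identities hold exactly", {
  withr::local_seed(12)
  d <- std_tbl(cbind(matrix(rnorm(60), 20, 3), rbinom(20, 1, 0.7)))
  d$x4 <- d$x4 - 1  # binary levels in standardized-like units, anchor at 0
  dc <- decompose_logit(random_mlp(4), d)
  for (r in dc$responses) {
    if (r$order == 1L) {
      expect_identical(r$values[r$grids[[1]] == 0], 0)
    } else {
      expect_identical(max(abs(r$values[r$grids[[1]] == 0, ])), 0)
      expect_identical(max(abs(r$values[, r$grids[[2]] == 0])), 0)
    }
  }
})

test_that("interpolation is exact on the grid, linear between and beyond", {
  r <- prnet:::new_response("x1", 1L, list(c(-1, 0, 1, 2)), c(2, 0, 4, 6),
                            "continuous")
  expect_equal(evaluate_response(r, c(-1, 0, 1, 2)), c(2, 0, 4, 6))
  expect_equal(evaluate_response(r, 0.5), mean(c(0, 4)))
  expect_equal(evaluate_response(r, 0), 0)
  # linear extrapolation from the terminal segments
  expect_equal(evaluate_response(r, 3), 8)
  expect_equal(evaluate_response(r, -2), 4)

  rb <- prnet:::new_response("z", 1L, list(c(0, 2.5)), c(0, 1.3), "binary")
  expect_equal(evaluate_response(rb, c(2.5, 0)), c(1.3, 0))
  expect_error(evaluate_response(rb, 1), "binary")

  r2 <- prnet:::new_response(c("x1", "x2"), 1:2,
                             list(c(0, 1), c(0, 2)),
                             matrix(c(0, 0, 0, 2), 2, 2), # s*t surface
                             c("continuous", "continuous"))
  expect_equal(evaluate_response(r2, cbind(0.5, 1)), 0.5)
  expect_equal(evaluate_response(r2, cbind(1, 2)), 2)
})

test_that("the full anchored expansion reconstructs any network exactly", {
  withr::local_seed(13)
  for (d_in in c(3, 4)) {
    m <- random_mlp(d_in, seed = d_in)
    X <- matrix(rnorm(20 * d_in), 20, d_in)
    g <- predict_logit(m, X)
    recon <- vapply(seq_len(nrow(X)), function(i) {
      oracle_full_reconstruction(m, X[i, ])
    }, 0)
    expect_lt(max(abs(recon - g)), 1e-8)
  }
})

test_that("order-2 truncation residual is the mass beyond pairs", {
  withr::local_seed(14)
  d <- std_tbl(matrix(rnorm(150), 50, 3))
  for (j in 1:3) d[[j]] <- d[[j]] - median(d[[j]])

  # additive surface: residual vanishes
  dc_add <- bb_decomp(function(X) X[, 1]^2 - 2 * X[, 2] + exp(X[, 3] / 4), d)
  expect_lt(max(abs(reconstruction_residual(dc_add, d)$residual)), 1e-8)

  # additive plus one pairwise term: still exact at order 2
  dc_pair <- bb_decomp(function(X) X[, 1]^2 + X[, 2] * X[, 3], d)
  expect_lt(attr(reconstruction_residual(dc_pair, d), "rms"), 1e-8)

  # a genuine 3-way surface: residual equals the brute-force 3-way component
  m <- random_mlp(3, seed = 99)
  dcm <- decompose_logit(m, d)
  res <- reconstruction_residual(dcm, d[1:10, ])
  threeway <- vapply(1:10, function(i) {
    oracle_subset_component(m, 1:3, as.numeric(d[i, 1:3]))
  }, 0)
  expect_equal(res$residual, threeway, tolerance = 1e-8)
})

test_that("decompositions serialize and reload with identical curves", {
  withr::local_seed(15)
  d <- std_tbl(cbind(x1 = rnorm(40), x2 = rnorm(40)))
  dc <- decompose_logit(random_mlp(2, seed = 3), d)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(dc, f)
  dc2 <- read_model(f)
  expect_identical(dc2$intercept, dc$intercept)
  for (nm in names(dc$responses)) {
    expect_identical(dc2$responses[[nm]]$values, dc$responses[[nm]]$values)
    expect_identical(dc2$responses[[nm]]$grids, dc$responses[[nm]]$grids)
  }
})
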