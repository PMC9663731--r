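test_that("reading a delimited table encodes, masks and validates", {
  sch <- registry_schema(
    tibble::tibble(name = c("age", "creatinine", "vent", "diagnosis"),
                   kind = c("continuous", "continuous", "binary", "categorical"),
                   levels = list(NULL, NULL, NULL, c("ICM", "NICM", "Other"))),
    outcome = "death")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,creatinine,vent,diagnosis,death",
               "50,100,0,ICM,0",
               "60,,1,NICM,1",
               "70,120,0,Other,0"), f)
  d <- read_registry(f, sch)

  expect_setequal(names(d), c("age", "creatinine", "vent",
                              "diagnosis.ICM", "diagnosis.NICM",
                              "diagnosis.Other", "death"))
  # exactly the blank creatinine cell is masked
  expect_identical(which(is.na(d$creatinine)), 2L)
  expect_false(anyNA(d[, setdiff(names(d), "creatinine")]))
  # indicators sum to one per row
  expect_equal(d$diagnosis.ICM + d$diagnosis.NICM + d$diagnosis.Other,
               rep(1, 3))

  # unknown level names column and level
  writeLines(c("age,creatinine,vent,diagnosis,death", "50,100,0,XXX,0"), f)
  expect_error(read_registry(f, sch), "diagnosis.*XXX")
  # non-numeric continuous cell names the row
  writeLines(c("age,creatinine,vent,diagnosis,death", "50,abc,0,ICM,0"), f)
  expect_error(read_registry(f, sch), "creatinine.*row 1")
  # missing outcome entries are rejected
  writeLines(c("age,creatinine,vent,diagnosis,death", "50,100,0,ICM,"), f)
  expect_error(read_registry(f, sch), "death")
})

test_that("anchors are medians for continuous and modes for binary columns", {
  d <- std_tbl(cbind(x1 = c(1, 2, 3, 4, 5), x2 = c(1, 0, 0, 0, 0)))
  a <- compute_anchor(d)
  expect_equal(a$anchor[a$column == "x1"], 3)
  expect_equal(a$anchor[a$column == "x2"], 0)
  expect_equal(a$scale, c(sd(c(1, 2, 3, 4, 5)), sd(c(1, 0, 0, 0, 0))))

  # even n: mean of the central pair
  a2 <- compute_anchor(std_tbl(cbind(x1 = c(1, 2, 3, 4))))
  expect_equal(a2$anchor, 2.5)

  # exact 50/50 binary tie anchors at 0
  a3 <- compute_anchor(std_tbl(cbind(z = c(0, 0, 1, 1))))
  expect_equal(a3$anchor, 0)

  # anchors use observed entries only
  a4 <- compute_anchor(std_tbl(cbind(x1 = c(1, 2, 3, NA, NA))))
  expect_equal(a4$anchor, 2)

  expect_error(compute_anchor(std_tbl(cbind(c1 = rep(2, 5)))), "constant")
})

test_that("standardization maps the anchor to zero and is invertible", {
  withr::local_seed(1)
  X <- cbind(x1 = rnorm(50, 10, 3), x2 = rbinom(50, 1, 0.3))
  X[3, 1] <- NA
  d <- std_tbl(X)
  a <- compute_anchor(d)
  s <- standardize(d, a)

  anchor_row <- std_tbl(matrix(a$anchor, 1, dimnames = list(NULL, a$column)))
  expect_equal(as.numeric(standardize(anchor_row, a)[1, ]), c(0, 0))

  back <- unstandardize(s, a)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
  expect_true(max(abs(back$x1 - d$x1), na.rm = TRUE) < 1e-10)
  expect_identical(is.na(s$x1), is.na(d$x1))

  # raw 5, anchor 3, scale 2 -> 1
  a_manual <- prnet:::new_anchor_tbl("x1", "continuous", 3, 2)
  expect_equal(standardize(std_tbl(cbind(x1 = 5)), a_manual)$x1, 1)

  expect_error(standardize(std_tbl(cbind(other = 1)), a), "match")
})

test_that("zero imputation touches only masked slots", {
  X <- cbind(x1 = c(0.5, NA, -1), x2 = c(NA, 0, 1))
  d <- std_tbl(X, y = c(0, 1, 0))
  out <- impute_zero(d)
  expect_equal(out$x1, c(0.5, 0, -1))
  expect_equal(out$x2, c(0, 0, 1))
  expect_false(anyNA(out))
  # no-missing input is returned unchanged
  full <- std_tbl(cbind(x1 = c(1, 2)), y = c(0, 1))
  expect_identical(as.data.frame(impute_zero(full)), as.data.frame(full))
})

test_that("donor imputation stacks m seeded copies drawn within strata", {
  withr::local_seed(42)
  n <- 40
  d <- tibble::tibble(
    x = c(rnorm(n / 2, 0), rnorm(n / 2, 10)),
    flag = rbinom(n, 1, 0.5),
    era = rep(c("old", "new"), each = n / 2),
    outcome = rbinom(n, 1, 0.2))
  d$x[c(3, 25)] <- NA
  attr(d, "outcome") <- "outcome"

  out <- impute_donors(d, strata = "era", m = 10, seed = 9)
  expect_equal(nrow(out), 10 * n)
  expect_equal(sort(unique(out$.imp)), 1:10)
  expect_false(anyNA(out$x))

  # every imputed value is an observed donor from the same stratum
  for (i in c(3, 25)) {
    strat <- d$era[i]
    pool <- d$x[d$era == strat & !is.na(d$x)]
    imputed <- out$x[rep(seq_len(n), 10) == i]
    expect_true(all(imputed %in% pool))
  }
  # observed entries never change
  obs <- which(!is.na(d$x))
  expect_identical(out$x[rep(seq_len(n), 10) %in% obs],
                   rep(d$x[obs], 10))

  # deterministic per seed; different seeds differ
  again <- impute_donors(d, strata = "era", m = 10, seed = 9)
  expect_identical(out, again)
  other <- impute_donors(d, strata = "era", m = 10, seed = 10)
  expect_false(identical(out$x, other$x))

  # a table with no missing values stacks identical copies
  full <- d; full$x[c(3, 25)] <- 1
  stacked <- impute_donors(full, strata = "era", m = 10, seed = 1)
  expect_equal(nrow(stacked), 10 * n)
  expect_identical(stacked$x, rep(full$x, 10))

  # a stratum without donors errors with both names
  bad <- d; bad$x[bad$era == "old"] <- NA
  expect_error(impute_donors(bad, strata = "era", m = 2, seed = 1), "old.*x")
})

test_that("schema files round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("outcome: death", "strata: era", "variables:",
               "  - name: age", "    kind: continuous", "    units: years",
               "  - name: diagnosis", "    kind: categorical",
               "    levels: [ICM, NICM]"), f)
  sch <- read_schema(f)
  expect_s3_class(sch, "prn_schema")
  expect_equal(attr(sch, "outcome"), "death")
  expect_equal(attr(sch, "strata"), "era")
  expect_equal(sch$levels[[2]], c("ICM", "NICM"))
  expect_error(registry_schema(data.frame(name = "a", kind = "weird")), "kind")
})
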