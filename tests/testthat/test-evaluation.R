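test_that("auroc follows the mid-rank pair-counting definition", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  # perfect separation
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # ties get half credit
  expect_equal(auroc(c(1, 1), c(0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "classes")

  # complement identity and invariance under monotone transforms
  withr::local_seed(1)
  s <- rnorm(200); y <- rbinom(200, 1, 0.4)
  expect_equal(auroc(s, y) + auroc(-s, y), 1)
  expect_equal(auroc(qlogis(plogis(s)), y), auroc(s, y))
  expect_equal(auroc(exp(s), y), auroc(s, y))

  # chance level under independence
  withr::local_seed(2)
  s2 <- rnorm(20000); y2 <- rbinom(20000, 1, 0.3)
  expect_lt(abs(auroc(s2, y2) - 0.5), 0.02)
})

test_that("auroc agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(3)
  for (i in 1:5) {
    s <- round(rnorm(80), 1)  # induce ties
    y <- rbinom(80, 1, 0.35)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("DeLong intervals are centred, shrink with n, and match pROC", {
  withr::local_seed(4)
  sim <- function(n) {
    y <- rbinom(n, 1, 0.4)
    s <- rnorm(n, mean = y)
    list(s = s, y = y)
  }
  d1 <- sim(200); d4 <- sim(800)
  ci1 <- delong_ci(d1$s, d1$y); ci4 <- delong_ci(d4$s, d4$y)
  expect_lt(ci1["lo"], attr(ci1, "auc"))
  expect_gt(ci1["hi"], attr(ci1, "auc"))
  expect_lt(ci4["hi"] - ci4["lo"], ci1["hi"] - ci1["lo"])

  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::ci.auc(d1$y, d1$s, method = "delong",
                                       direction = "<"))
  expect_equal(unname(ci1["lo"]), ref[1], tolerance = 1e-8)
  expect_equal(unname(ci1["hi"]), ref[3], tolerance = 1e-8)
})

test_that("DeLong variance matches the bootstrap on a seeded sample", {
  withr::local_seed(5)
  n <- 200
  y <- rbinom(n, 1, 0.35)
  s <- rnorm(n, mean = 0.8 * y)
  se <- attr(delong_ci(s, y), "se")
  boot <- vapply(1:2000, function(b) {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(y[i])) < 2) return(NA_real_)
    auroc(s[i], y[i])
  }, 0)
  expect_lt(abs(se^2 / var(boot, na.rm = TRUE) - 1), 0.2)
})

test_that("the paired DeLong test detects and respects equality", {
  withr::local_seed(6)
  y <- rbinom(500, 1, 0.4)
  s <- rnorm(500, mean = y)
  expect_warning(out <- delong_test(s, s, y), "Identical")
  expect_equal(out$p.value, 1)
  expect_equal(out$difference, 0)

  # reversing a discriminative score maximally separates the AUROCs
  strong <- delong_test(s, 1 - s, y)
  expect_lt(strong$p.value, 1e-6)

  skip_if_not_installed("pROC")
  s2 <- rnorm(500, mean = 0.5 * y)
  ref <- suppressMessages(pROC::roc.test(
    pROC::roc(y, s, direction = "<", quiet = TRUE),
    pROC::roc(y, s2, direction = "<", quiet = TRUE),
    method = "delong"))
  mine <- delong_test(s, s2, y)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("Hosmer-Lemeshow groups by deciles of risk and uses g-2 df", {
  withr::local_seed(7)
  p <- runif(5000, 0.05, 0.6)
  y <- rbinom(5000, 1, p)
  hl <- hosmer_lemeshow(p, y, groups = 10)
  expect_equal(hl$df, 8)
  expect_equal(nrow(hl$table), 10)
  expect_lt(max(hl$table$n) - min(hl$table$n), 5)
  expect_gt(hl$p.value, 0.001)  # well-calibrated by construction

  # observed equal to expected in every group gives statistic zero
  p0 <- rep(c(0.2, 0.4, 0.6, 0.8), each = 10)
  y0 <- as.numeric(sequence(rep(10, 4)) <= c(2, 4, 6, 8)[rep(1:4, each = 10)])
  hl0 <- hosmer_lemeshow(p0, y0, groups = 4)
  expect_equal(hl0$statistic, 0)
  expect_equal(hl0$p.value, 1)

  expect_error(hosmer_lemeshow(p, y, groups = 2), "at least 3")
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1), groups = 3), "strictly")
})

test_that("calibration summary: E/O, CITL and grouped rates", {
  withr::local_seed(8)
  p <- runif(50000, 0.02, 0.4)
  y <- rbinom(50000, 1, p)
  cal <- calibration_summary(p, y)
  expect_lt(abs(cal$eo_ratio - 1), 0.05)
  expect_lt(abs(cal$citl), 0.05)
  expect_lt(abs(cal$slope - 1), 0.1)
  expect_equal(nrow(cal$groups), 10)
  expect_true(all(cal$groups$lo <= cal$groups$obs_rate &
                    cal$groups$obs_rate <= cal$groups$hi))

  # doubling the claimed risk doubles E/O on a rare outcome
  cal2 <- calibration_summary(pmin(2 * p, 0.99), y)
  expect_lt(abs(cal2$eo_ratio - 2), 0.1)

  expect_error(calibration_summary(p, rep(0, length(p))), "events")
})

test_that("the evaluation report collates discrimination and calibration", {
  withr::local_seed(9)
  n <- 1000
  y <- rbinom(n, 1, 0.3)
  good <- plogis(qlogis(0.3) + 1.2 * y + rnorm(n))
  weak <- plogis(qlogis(0.3) + 0.2 * y + rnorm(n))
  rep_tbl <- evaluate_scores(tibble::tibble(outcome = y, good = good,
                                            weak = weak),
                             c("good", "weak"))
  expect_equal(nrow(rep_tbl), 2)
  expect_true(is.na(rep_tbl$delong_p_vs_ref[1]))
  expect_false(is.na(rep_tbl$delong_p_vs_ref[2]))
  expect_gt(rep_tbl$auroc[1], rep_tbl$auroc[2])
  expect_true(all(rep_tbl$ci_lo <= rep_tbl$auroc &
                    rep_tbl$auroc <= rep_tbl$ci_hi))
})
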