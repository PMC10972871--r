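test_that("monoploid size and ploidy formulas are mutual inverses", {
  expect_equal(kew_one_cx(1.0, 2), 1.0)   # 1C = 1Cx for diploids
  expect_equal(kew_one_cx(4.0, 4), 2.0)
  expect_equal(kew_one_cx(3.0, 6), 1.0)
  expect_error(kew_one_cx(1.0, 1), ">= 2")

  expect_equal(estimate_ploidy(1.0, 1.0), 2.0)
  expect_equal(estimate_ploidy(2.0, 1.0), 4.0)
  expect_identical(estimate_ploidy(4.0, 1.0, round_result = TRUE), 8L)

  for (p in 2:8)
    expect_equal(estimate_ploidy(3.2, kew_one_cx(3.2, p)), p)
})

test_that("cytotype consensus accepts low variation and rejects high", {
  one <- cytotype_consensus(1.7, 2)
  expect_true(one$accepted)
  expect_equal(one$one_cx, 1.7)
  expect_equal(one$variation, 0)

  # 1Cx {1.0, 1.05}: variation 0.05/1.025 = 4.88%
  ok <- cytotype_consensus(c(1.0, 2.1), c(2, 4))
  expect_true(ok$accepted)
  expect_equal(ok$one_cx, 1.025)
  expect_equal(ok$variation, 0.05 / 1.025, tolerance = 1e-12)

  # 1Cx {1.0, 1.2}: variation 0.2/1.1 = 18.2% > 10%
  bad <- cytotype_consensus(c(1.0, 2.4), c(2, 4))
  expect_false(bad$accepted)
  expect_true(is.na(bad$one_cx))
  expect_equal(bad$variation, 0.2 / 1.1, tolerance = 1e-12)
})

test_that("theoretical depth is L over the reference monoploid size", {
  expect_equal(theoretical_depth(1e9, 5e8), 2)
  expect_equal(theoretical_depth(0, 123), 0)
  expect_equal(theoretical_depth(1e9, 1e9), 1)
  expect_error(theoretical_depth(1, 0), "positive")
})

test_that("robust slope recovers exact and noisy lines", {
  x <- c(0.2, 0.5, 1, 2, 4)
  fit <- robust_slope(x, 1.56 * x)
  expect_equal(fit$beta, 1.56, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_downweighted, 0L)

  set.seed(111)
  x <- runif(20, 0.1, 3)
  y <- 1.5 * x + rnorm(20, 0, 0.01)
  fit <- robust_slope(x, y)
  expect_true(fit$beta > 1.45 && fit$beta < 1.55)
  ols <- sum(x * y) / sum(x^2)          # OLS-through-origin oracle
  expect_equal(fit$beta, ols, tolerance = 0.02)

  expect_error(robust_slope(1:2, 1:2), "3 calibration points")
  expect_error(robust_slope(c(-1, 1, 2), c(1, 1, 2)), "positive")
})

test_that("robust slope resists gross outliers that wreck OLS", {
  set.seed(112)
  x <- runif(20, 0.2, 3)
  y <- 1.5 * x + rnorm(20, 0, 0.02)
  y[1:2] <- 10 * x[1:2]
  fit <- robust_slope(x, y)
  expect_lt(abs(fit$beta - 1.5) / 1.5, 0.05)
  expect_equal(fit$n_downweighted, 2L)
  ols <- sum(x * y) / sum(x^2)
  expect_gt(ols, 1.8)
})

test_that("robust slope agrees with an MM-type reference fitter", {
  skip_if_not_installed("MASS")
  set.seed(113)
  x <- runif(30, 0.2, 3)
  y <- 1.4 * x + rnorm(30, 0, 0.05)
  y[1] <- 5 * x[1]
  fit <- robust_slope(x, y)
  ref <- MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 0.02)
})

test_that("slope is scale equivariant in the response", {
  set.seed(114)
  x <- runif(15, 0.2, 3)
  y <- 1.3 * x + rnorm(15, 0, 0.05)
  b1 <- robust_slope(x, y)$beta
  b3 <- robust_slope(x, 3 * y)$beta
  expect_equal(b3, 3 * b1, tolerance = 1e-6)
})

test_that("per-group calibration emits one slope per group plus pooled", {
  x <- c(0.3, 0.8, 1.5, 2.5)
  pts <- data.frame(
    group = rep(c("g1", "g2"), each = 4),
    scp_depth = rep(x, 2),
    theoretical_depth = c(1.2 * x, 1.8 * x))
  tab <- calibrate_groups(pts)
  expect_equal(slope_lookup(tab, "g1"), 1.2, tolerance = 1e-8)
  expect_equal(slope_lookup(tab, "g2"), 1.8, tolerance = 1e-8)
  expect_true("all" %in% tab$group)
  expect_true("default" %in% tab$group)
  pooled <- tab$slope[tab$group == "all"]
  expect_true(pooled > 1.2 && pooled < 1.8)

  # a 2-point group is skipped with a warning
  pts2 <- rbind(pts, data.frame(group = "tiny", scp_depth = c(1, 2),
                                theoretical_depth = c(1.5, 3)))
  expect_warning(tab2 <- calibrate_groups(pts2), "tiny")
  expect_false("tiny" %in% tab2$group)

  # a single group: its slope equals the pooled fit
  tab3 <- calibrate_groups(pts[pts$group == "g1", ])
  expect_equal(tab3$slope[tab3$group == "all"],
               slope_lookup(tab3, "g1"), tolerance = 1e-10)
})

test_that("picogram C-values convert at 978 Mb/pg", {
  expect_equal(pg_to_mb(1), 978)
  expect_equal(pg_to_mb(0.5), 489)
})
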