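# Comparison statistics versus closed forms and independent oracles.

test_that("goodness of fit: proportional counts give zero, roads are extreme", {
  z <- chisqGof(c(30, 60, 10), c(0.3, 0.6, 0.1))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  r <- chisqGof(c(31, 69), c(0.01, 0.99))
  expect_equal(r$statistic, 30^2 / 1 + 30^2 / 99, tolerance = 1e-12)  # 909.09
  expect_lt(r$p_value, 0.001)
  expect_error(chisqGof(c(1, 1), c(0, 1)), "zero expectation")
})

test_that("goodness of fit matches chisq.test as an oracle", {
  set.seed(29)
  for (k in 1:10) {
    p <- c(0.2, 0.5, 0.3)
    x <- as.vector(rmultinom(1, 50, p))
    mine <- chisqGof(x, p)
    ref <- suppressWarnings(chisq.test(x, p = p))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("2x2 chi-square matches the textbook formula and symmetry", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  mine <- chisq2x2(tab)
  n <- sum(tab)
  oracle <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  expect_equal(mine$statistic, oracle, tolerance = 1e-12)
  expect_equal(chisq2x2(tab[2:1, ])$statistic, mine$statistic)
  expect_equal(chisq2x2(matrix(c(5, 5, 10, 10), 2))$statistic, 0)
  ref <- chisq.test(tab, correct = TRUE)
  expect_equal(chisq2x2(tab, correct = TRUE)$statistic,
               unname(ref$statistic), tolerance = 1e-12)
  expect_error(chisq2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("Poisson rate comparison: identity, closed form, GLM oracle", {
  eq <- poissonRateComparison(c(5, 7, 9), c(9, 5, 7))
  expect_equal(eq$log_rate_ratio, 0)
  expect_equal(eq$p.value, 1)

  a <- rep(439, 60); b <- rep(1356, 60)
  rc <- poissonRateComparison(a, b)
  expect_equal(unname(rc$estimate["rate_ratio"]), 1356 / 439, tolerance = 1e-12)
  expect_equal(rc$log_rate_ratio, log(1356 / 439), tolerance = 1e-12)
  expect_equal(rc$se_log_rr, sqrt(1 / 26340 + 1 / 81360), tolerance = 1e-12)

  set.seed(30)
  for (k in 1:10) {
    x <- rpois(25, 8); y <- rpois(30, 15)
    mine <- poissonRateComparison(x, y)
    fit <- glm(c(x, y) ~ rep(c(0, 1), c(25, 30)), family = poisson(), control = glm.control(epsilon = 1e-12))
    co <- summary(fit)$coefficients
    expect_equal(mine$log_rate_ratio, unname(co[2, 1]), tolerance = 1e-6)
    expect_equal(mine$se_log_rr, unname(co[2, 2]), tolerance = 1e-6)
    expect_equal(unname(mine$statistic), unname(co[2, 3]), tolerance = 1e-6)
  }
  expect_error(poissonRateComparison(c(0, 0), c(1, 2)), "positive sum")
})

test_that("bootstrap correlation: exact linearity, determinism, errors", {
  x <- 1:20
  b <- bootstrapPearson(x, 2 * x + 1, B = 500, seed = 3)
  expect_equal(b$r, 1)
  expect_equal(b$ci, c(1, 1))
  expect_error(bootstrapPearson(rep(1, 10), rnorm(10)), "constant")
  set.seed(99)
  x <- rnorm(15); y <- rnorm(15)
  expect_identical(bootstrapPearson(x, y, B = 400, seed = 11)$ci,
                   bootstrapPearson(x, y, B = 400, seed = 11)$ci)
})

test_that("bootstrap percentile interval approximately covers the truth", {
  set.seed(31)
  rho <- 0.4
  cover <- vapply(1:200, function(k) {
    z <- rnorm(60); e <- rnorm(60)
    x <- z
    y <- rho * z + sqrt(1 - rho^2) * e
    ci <- bootstrapPearson(x, y, B = 400, seed = k)$ci
    ci[1] <= rho && rho <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  expect_lte(mean(cover), 0.99)
})

test_that("Fisher z difference matches the direct formula", {
  eqz <- fisherZDifference(0.4, 50, 0.4, 80)
  expect_equal(unname(eqz$statistic), 0)
  expect_equal(eqz$p.value, 1)
  z1 <- fisherZDifference(0.38, 60, 0.06, 60)
  expect_equal(unname(z1$statistic),
               (atanh(0.38) - atanh(0.06)) / sqrt(2 / 57), tolerance = 1e-12)
  expect_equal(unname(z1$statistic), 1.815, tolerance = 1e-3)
  z2 <- fisherZDifference(0.5, 30, 0, 30)
  expect_equal(unname(z2$statistic), 0.549306 / sqrt(2 / 27), tolerance = 1e-4)
  expect_error(fisherZDifference(1, 30, 0, 30))
  expect_error(fisherZDifference(0.5, 3, 0, 30))
})

test_that("signed rank: all-positive differences give T = 0 and exact p", {
  w <- wilcoxonSignedRank(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(unname(w$statistic), 0)
  expect_true(w$exact)
  expect_equal(w$p.value, 2 / 64)           # one tail 1/64, two-sided
  expect_identical(w$n_effective, 6L)
})

test_that("signed rank is symmetric under sign reversal", {
  set.seed(32)
  for (k in 1:10) {
    a <- rpois(15, 6); b <- rpois(15, 6)
    if (all(a == b)) next
    w1 <- wilcoxonSignedRank(a, b)
    w2 <- wilcoxonSignedRank(b, a)
    expect_equal(w1$p.value, w2$p.value, tolerance = 1e-12)
    expect_equal(unname(w1$statistic), unname(w2$statistic))
  }
})

test_that("signed rank drops double-zero pairs as the protocol requires", {
  a <- c(0, 0, 3, 5, 2)
  b <- c(0, 0, 1, 2, 4)
  w <- wilcoxonSignedRank(a, b)
  expect_identical(w$n_effective, 3L)
  expect_error(wilcoxonSignedRank(c(0, 1), c(0, 1)), "zero")
})

test_that("signed rank agrees with wilcox.test as an oracle", {
  set.seed(33)
  for (k in 1:10) {
    a <- rnorm(20); b <- rnorm(20)    # continuous: no ties, no zeros
    mine <- wilcoxonSignedRank(a, b, exact_max = 0L)
    ref <- wilcox.test(a, b, paired = TRUE, correct = TRUE, exact = FALSE)
    # the plain continuity-corrected deviate reproduces wilcox.test exactly;
    # the reported p additionally carries the small-sample kurtosis term
    expect_equal(2 * pnorm(-abs(mine$z_approx)), ref$p.value,
                 tolerance = 1e-10)
    expect_lt(abs(mine$p.value - ref$p.value), 0.015)
    exact <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_lt(abs(mine$p.value - exact), 0.002)
  }
})

test_that("exact enumeration matches the normal tail closely at n = 12", {
  set.seed(34)
  for (k in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    exact <- wilcoxonSignedRank(a, b, exact_max = 12L)
    approx <- wilcoxonSignedRank(a, b, exact_max = 0L)
    expect_true(exact$exact); expect_false(approx$exact)
    expect_lt(abs(exact$p.value - approx$p.value), 0.01)
  }
})
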