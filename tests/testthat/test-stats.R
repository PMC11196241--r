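# Statistical primitives vs enumeration oracles and base-R cross-checks.

test_that("Mann-Whitney handles extreme, symmetric and tied cases", {
  expect_equal(mannWhitney(c(1, 2), c(3, 4))$U, 0)  # complete separation
  same <- mannWhitney(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  tied <- mannWhitney(rep(3, 4), rep(3, 5))
  expect_equal(tied$z, 0)
  expect_equal(tied$p, 1)
  # direction: x below y gives negative z
  expect_lt(mannWhitney(1:5, 6:10)$z, 0)
  expect_gt(mannWhitney(6:10, 1:5)$z, 0)
})

test_that("U equals exhaustive enumeration; normal p close to exact p", {
  set.seed(40)
  for (n1 in c(2, 3, 4, 5)) {
    n2 <- sample(1:(10 - n1), 1)
    x <- sample(1:8, n1, replace = TRUE)  # replace=TRUE exercises ties
    y <- sample(1:8, n2, replace = TRUE)
    mw <- mannWhitney(x, y)
    orc <- oracleMannWhitney(x, y)
    expect_equal(mw$U, orc$U)
    # the normal approximation tracks the exact p on untied samples with
    # both group sizes >= 3 (it degrades below that and under heavy ties)
    if (min(n1, n2) >= 3) {
      v <- sample(1:30, n1 + n2)
      expect_lt(abs(mannWhitney(v[1:n1], v[-(1:n1)])$p -
                    oracleMannWhitney(v[1:n1], v[-(1:n1)])$pExact), 0.05)
    }
  }
  # interleaved example against the permutation oracle
  x <- c(1, 3, 5, 7); y <- c(2, 4, 6, 8)
  expect_equal(mannWhitney(x, y)$U, oracleMannWhitney(x, y)$U)
})

test_that("Mann-Whitney agrees with wilcox.test", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mw <- mannWhitney(x, y)
  wt <- wilcox.test(x, y, correct = TRUE, exact = FALSE)
  expect_equal(mw$U, unname(wt$statistic))
  expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
})

test_that("group swap flips statistics and preserves p-values", {
  set.seed(42)
  x <- rnorm(12); y <- rnorm(15, 0.3)
  mw1 <- mannWhitney(x, y); mw2 <- mannWhitney(y, x)
  expect_equal(mw1$z, -mw2$z)
  expect_equal(mw1$p, mw2$p)
  t1 <- twoSampleT(x, y); t2 <- twoSampleT(y, x)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
})

test_that("t tests: identity, summary-statistics formula oracle, Welch", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  tt <- twoSampleT(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  set.seed(43)
  a <- rnorm(14, 1); b <- rnorm(11)
  ts <- tFromSummary(mean(a), sd(a), 14, mean(b), sd(b), 11)
  td <- twoSampleT(a, b)
  expect_equal(ts$t, td$t)
  expect_equal(ts$p, td$p)
  tw <- twoSampleT(a, b, welch = TRUE)
  expect_equal(tw$p, t.test(a, b)$p.value)
})

test_that("chi-square matches the closed form and degenerate cases", {
  # proportional table: independence
  expect_equal(chiSquare2x2(matrix(c(10, 5, 20, 10), 2))$chi2, 0)
  # closed form N(ad-bc)^2 / margin product
  tab <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(chiSquare2x2(tab)$chi2, 10)
  set.seed(44)
  t2 <- matrix(rpois(4, 20) + 1, 2)
  cf <- sum(t2) * (t2[1, 1] * t2[2, 2] - t2[1, 2] * t2[2, 1])^2 /
    prod(rowSums(t2), colSums(t2))
  expect_equal(chiSquare2x2(t2)$chi2, cf)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("BH step-up matches the hand computation and is order-invariant", {
  expect_equal(bhFdr(0.03)$q, 0.03)  # m = 1
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$significant))
  set.seed(45)
  p <- runif(50)^2
  perm <- sample(50)
  expect_equal(bhFdr(p)$q[perm], bhFdr(p[perm])$q)
  expect_identical(bhFdr(numeric(0))$q, numeric(0))
})

test_that("Spearman rho matches the rank formula on n = 6", {
  x <- c(10, 20, 30, 40, 50, 60)
  y <- c(12, 31, 25, 44, 70, 58)  # ranks 1,3,2,4,6,5: d^2 sum = 4
  sp <- spearmanRho(x, y)
  expect_equal(sp$rho, 1 - 6 * 4 / (6 * 35))
  expect_equal(spearmanRho(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearmanRho(1:6, -(1:6))$rho, -1)
  ct <- cor.test(x, y, method = "spearman")
  expect_equal(sp$rho, unname(ct$estimate))
})

test_that("partial Spearman equals the precision-matrix oracle", {
  set.seed(46)
  for (rep in 1:5) {
    z1 <- rnorm(30); z2 <- rnorm(30)
    x <- z1 + 0.8 * z2 + rnorm(30, 0, 0.5)
    y <- -z1 + 0.5 * z2 + rnorm(30, 0, 0.5)
    ps <- partialSpearman(x, y, cbind(a = z1, b = z2))
    expect_equal(ps$rho, oraclePartialSpearman(x, y, cbind(z1, z2)),
                 tolerance = 1e-10)
  }
})

test_that("partial Spearman degenerate covariates behave as specified", {
  set.seed(47)
  x <- rnorm(20); y <- rnorm(20)
  # constant covariate is a no-op adjustment (df loses the dropped column)
  ps0 <- partialSpearman(x, y, cbind(c1 = rep(1, 20)))
  expect_equal(ps0$rho, spearmanRho(x, y)$rho)
  # covariate identical to x absorbs it fully
  expect_equal(partialSpearman(x, y, cbind(x))$rho, 0)
  # two copies of the same covariate are collinear
  expect_error(partialSpearman(x, y, cbind(a = y, b = y)), "a, b")
})
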