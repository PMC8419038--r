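test_that("group comparison couples Kruskal-Wallis with Bonferroni pairwise MW", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  gc <- groupCompare(g)
  expect_equal(unname(gc$omnibus$statistic), 0)
  expect_identical(gc$m, 3L)
  expect_equal(gc$pairwise$p_adj, pmin(1, 3 * gc$pairwise$p))
  expect_true(all(gc$pairwise$p_adj >= gc$pairwise$p))
  expect_true(all(gc$pairwise$p_adj <= 1))
  expect_error(groupCompare(list(1:3)), "2 groups")
  expect_error(groupCompare(list(1:3, numeric(0))), "at least 2 observations")
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  p1 <- groupCompare(list(x, y))$pairwise$p
  p2 <- groupCompare(list(exp(x), exp(y)))$pairwise$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("paired tests detect a constant shift and reject degenerate input", {
  set.seed(2)
  x0 <- rnorm(20, 10, 1)
  x7 <- x0 + 2
  res <- pairedCompare(x0, x7, "paired_t")
  # oracle: with zero-variance differences jittered, t = mean(d)/(sd(d)/sqrt(n))
  dj <- (x7 + rnorm(20, 0, 1e-9)) - x0
  tOracle <- mean(dj) / (sd(dj) / sqrt(20))
  pOracle <- 2 * stats::pt(abs(tOracle), 19, lower.tail = FALSE)
  expect_lt(res$p, 1e-6)
  expect_lt(pOracle, 1e-6)
  wc <- pairedCompare(x0, x7, "wilcoxon")
  expect_lt(wc$p, 0.001)
  expect_error(pairedCompare(x0, x0, "wilcoxon"), "degenerate")
})

test_that("paired t-test holds its nominal level under the null", {
  set.seed(11)
  rej <- replicate(2000, {
    x0 <- rnorm(15); x7 <- x0 + rnorm(15)
    pairedCompare(x0, x7, "paired_t")$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("correlation method is gated by Shapiro-Wilk normality", {
  set.seed(3)
  x <- rnorm(40)
  g1 <- gatedCorrelation(x, 2 * x + 1)
  expect_identical(g1$method, "pearson")
  expect_equal(g1$r, 1)

  xt <- rt(40, df = 1)  # heavy-tailed: fails normality
  g2 <- gatedCorrelation(xt, xt^3)
  expect_identical(g2$method, "spearman")
  expect_equal(g2$r, 1)  # rank oracle: x^3 preserves order exactly

  expect_error(gatedCorrelation(1:3, 1:3), "at least 4")
  expect_error(gatedCorrelation(rep(1, 10), rnorm(10)), "constant")
})

test_that("biexponential fit recovers both half-lives from clean data", {
  t <- c(1, 6, 12, 36, 120, 168)
  pk <- generatePKSeries(8, 2, 2, 30, timepoints = t, noiseSD = 0)
  f <- fitBiexponential(pk$time_h, pk$intensity)
  expect_lt(abs(f$thalfFast - 2) / 2, 0.02)
  expect_lt(abs(f$thalfSlow - 30) / 30, 0.02)
  expect_gt(f$lambda1, f$lambda2)
  expect_equal(f$thalfFast, log(2) / f$lambda1)

  # single-component data: the slow (terminal) half-life is the true one
  pk1 <- generatePKSeries(0, 1, 5, 10, timepoints = t, noiseSD = 0)
  f1 <- fitBiexponential(pk1$time_h, pk1$intensity)
  expect_lt(abs(f1$thalfSlow - 10) / 10, 0.01)

  expect_error(fitBiexponential(t, c(1, 2, 0, 1, 1, 1)), "> 0")
  expect_error(fitBiexponential(1:4, rep(1, 4)), "5 time points")
})

test_that("time-unit rescaling doubles rates and halves half-lives", {
  t <- c(1, 6, 12, 36, 120, 168)
  y <- generatePKSeries(8, 2, 2, 30, timepoints = t, noiseSD = 0)$intensity
  f <- fitBiexponential(t, y)
  f2 <- fitBiexponential(t / 2, y)
  expect_equal(f2$lambda1, 2 * f$lambda1, tolerance = 1e-6)
  expect_equal(f2$thalfSlow, f$thalfSlow / 2, tolerance = 1e-6)
})

test_that("both half-lives are recovered under multiplicative noise", {
  t <- c(1, 6, 12, 36, 120, 168)
  clean <- 8 * 2^(-t / 2) + 2 * 2^(-t / 30)
  errs <- vapply(1:60, function(s) {
    set.seed(s)
    f <- fitBiexponential(t, clean * exp(rnorm(6, 0, 0.05)))
    c(abs(f$thalfFast - 2) / 2, abs(f$thalfSlow - 30) / 30)
  }, numeric(2))
  expect_lte(median(errs[1, ]), 0.15)
  expect_lte(median(errs[2, ]), 0.15)
})
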