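# The exact-test kernel against brute-force enumeration and the base-R
# reference implementations (used only as independent cross-checks).

test_that("exact signed-rank p equals full sign-pattern enumeration", {
  # smallest attainable two-sided p at n = 5 with all-positive differences
  res <- wilcoxonSignedRank(c(1.2, 0.8, 2.1, 0.4, 1.7))
  expect_identical(res$p.value, 2 / 32)
  expect_true(res$exact)
  # zero differences dropped; all-zero degenerate
  expect_equal(wilcoxonSignedRank(rep(0, 4))$p.value, 1)
  expect_true(wilcoxonSignedRank(rep(0, 4))$degenerate)
  # random instances, with and without ties, vs 2^n enumeration
  set.seed(401)
  for (i in 1:40) {
    n <- sample(3:11, 1)
    d <- if (i %% 2) round(rnorm(n), 1) else sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    res <- wilcoxonSignedRank(d)
    ora <- oracleSignedRank(d)
    expect_equal(res$p.value, ora$p, tolerance = 1e-12)
    expect_equal(res$statistic, ora$W)
  }
})

test_that("signed-rank normal approximation is close to exact at the regime boundary", {
  set.seed(402)
  worst <- 0
  for (i in 1:20) {
    d <- rnorm(26)
    pEx <- wilcoxonSignedRank(d, exactMax = 30)$p.value
    pAp <- wilcoxonSignedRank(d, exactMax = 10)$p.value
    worst <- max(worst, abs(pEx - pAp))
  }
  expect_lt(worst, 0.01)
})

test_that("exact rank-sum p equals label-assignment enumeration", {
  # complete separation at 4 vs 4: p = 2/70
  expect_equal(wilcoxonRankSum(1:4, 11:14)$p.value, 2 / 70)
  # identical groups give p = 1
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  set.seed(403)
  for (i in 1:30) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    tie <- i %% 2 == 0
    x <- if (tie) sample(1:5, nx, replace = TRUE) else rnorm(nx)
    y <- if (tie) sample(1:5, ny, replace = TRUE) else rnorm(ny)
    res <- wilcoxonRankSum(x, y)
    ora <- oracleRankSum(x, y)
    expect_equal(res$p.value, ora$p, tolerance = 1e-12)
    if (!tie) {
      ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
      expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("two-sided p is invariant to swapping group labels", {
  set.seed(404)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(7)
    expect_equal(wilcoxonRankSum(x, y)$p.value,
                 wilcoxonRankSum(y, x)$p.value, tolerance = 1e-12)
    expect_equal(tTestTwoTailed(x, y)$p.value,
                 tTestTwoTailed(y, x)$p.value, tolerance = 1e-12)
  }
})

test_that("Fisher exact matches hypergeometric enumeration and fisher.test", {
  res <- fisherExactTest(rbind(c(5, 5), c(15, 75)))
  expect_equal(res$odds.ratio, 5)                     # (5*75)/(5*15)
  expect_false(res$or.flagged)
  # identical row proportions: independence, p = 1
  expect_equal(fisherExactTest(rbind(c(2, 4), c(3, 6)))$p.value, 1)
  set.seed(405)
  for (i in 1:50) {
    tb <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (sum(tb) == 0) tb[1, 1] <- 1
    res <- fisherExactTest(tb)
    expect_equal(res$p.value, oracleFisher(tb[1, 1], tb[1, 2],
                                           tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    ref <- fisher.test(tb)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
  }
  # zero-cell odds ratios are flagged
  expect_true(is.infinite(fisherExactTest(rbind(c(3, 0), c(0, 3)))$odds.ratio))
  expect_true(fisherExactTest(rbind(c(3, 0), c(0, 3)))$or.flagged)
  expect_error(fisherExactTest(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("Kendall tau-b and exact p match brute-force permutation enumeration", {
  expect_equal(kendallTauB(1:6, 1:6)$tau, 1)
  expect_equal(kendallTauB(1:6, 6:1)$tau, -1)
  deg <- kendallTauB(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 1)
  set.seed(406)
  for (i in 1:15) {
    n <- sample(4:6, 1)
    x <- sample(c(-1, 0, 1), n, replace = TRUE)
    y <- sample(c(-1, 0, 1), n, replace = TRUE)
    if (length(unique(x)) == 1) x[1] <- x[1] + 1
    if (length(unique(y)) == 1) y[1] <- y[1] + 1
    res <- kendallTauB(x, y)
    expect_equal(res$S, oracleTauS(x, y))
    expect_equal(res$p.value, oracleTauExactP(x, y), tolerance = 1e-12)
    expect_equal(res$tau, unname(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
  # ternary n = 8 case against the full 8! enumeration
  x <- c(-1, 0, 1, 1, 0, -1, 1, 0)
  y <- c(-1, 1, 1, 0, 0, -1, 1, -1)
  res <- kendallTauB(x, y)
  expect_equal(res$p.value, oracleTauExactP(x, y), tolerance = 1e-12)
})

test_that("tau-b normal approximation agrees with cor.test on tied data", {
  set.seed(407)
  for (i in 1:10) {
    x <- sample(c(-1, 0, 1), 40, replace = TRUE, prob = c(.2, .6, .2))
    y <- sample(c(-1, 0, 1), 40, replace = TRUE, prob = c(.2, .6, .2))
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    res <- kendallTauB(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(res$tau, unname(ref$estimate), tolerance = 1e-9)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("pooled t test matches the closed form and t.test", {
  res <- tTestTwoTailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$p.value, 0.0213, tolerance = 1e-3)
  expect_equal(tTestTwoTailed(c(2, 3, 4), c(2, 3, 4))$statistic, 0)
  expect_equal(tTestTwoTailed(c(2, 3, 4), c(2, 3, 4))$p.value, 1)
  set.seed(408)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(8, 0.5)
    ref <- t.test(x, y, var.equal = TRUE)
    res <- tTestTwoTailed(x, y)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  }
  expect_true(tTestTwoTailed(c(1, 1, 1), c(1, 1))$degenerate)
})

test_that("BH adjustment reproduces the hand-worked step-up values", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in p within a vector
  set.seed(409)
  p <- runif(50)
  f <- fdrAdjust(p)
  expect_true(all(diff(f[order(p)]) >= -1e-15))
})
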