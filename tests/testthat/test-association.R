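test_that("rank transform follows the average-of-positions tie rule", {
  expect_equal(rankTransform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rankTransform(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_equal(rankTransform(c(7, 3, 3, 9)), c(3, 1.5, 1.5, 4))
  set.seed(1)
  for (i in 1:20) {
    x <- sample(round(rnorm(12), 1), 12, replace = TRUE)
    r <- rankTransform(x)
    expect_equal(sum(r), 12 * 13 / 2)
    expect_equal(r, oracleRank(x))
  }
  expect_error(rankTransform(c(1, NA)), class = "invalidInputError")
  expect_error(rankTransform(c(1, Inf)), class = "invalidInputError")
})

test_that("correlation measures reproduce worked examples", {
  expect_equal(statistic(associationTest(c(1, 2, 3, 4), c(2, 4, 6, 8),
                                         "pearson")), 1)
  expect_equal(statistic(associationTest(c(1, 2, 3, 4), c(4, 3, 2, 1),
                                         "pearson")), -1)
  # hand evaluation for x = 1:4, y = (1,3,2,4): cov = 2/3 of var, r = 0.8
  r <- associationTest(1:4, c(1, 3, 2, 4), "pearson")
  expect_equal(statistic(r), 0.8)
  expect_equal(pValue(r), 2 * pt(-0.8 * sqrt(2 / (1 - 0.64)), df = 2))
  # rho for y a permutation (3,1,2) of x=1:3 via 1 - 6*sum(d^2)/(n(n^2-1));
  # computed at n >= 4 to respect the precondition: x=1:4, y=(2,1,4,3)
  # d = (-1,1,-1,1), sum d^2 = 4, rho = 1 - 24/60 = 0.6
  expect_equal(statistic(associationTest(1:4, c(2, 1, 4, 3), "spearman")), 0.6)
  # tau from enumerating all six pairs of x=1:4, y=(2,1,4,3): C=4, D=2
  expect_equal(statistic(associationTest(1:4, c(2, 1, 4, 3), "kendall")),
               1 / 3)
  expect_equal(statistic(associationTest(1:5, 1:5, "kendall")), 1)
  expect_equal(statistic(associationTest(1:5, 5:1, "kendall")), -1)
})

test_that("Kendall p-value matches the reference normal approximation", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    if (i > 5) { x <- round(x, 1); y <- round(y, 1) }  # force ties
    mine <- associationTest(x, y, "kendall")
    ref <- suppressWarnings(cor.test(x, y, method = "kendall",
                                     exact = FALSE))
    expect_equal(statistic(mine), unname(ref$estimate), tolerance = 1e-12)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
  }
})

test_that("Pearson and Spearman match cor() and the t-based p-value", {
  set.seed(43)
  n <- 30
  x <- rnorm(n); y <- x + rnorm(n)
  pr <- associationTest(x, y, "pearson")
  ct <- cor.test(x, y)
  expect_equal(statistic(pr), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pValue(pr), ct$p.value, tolerance = 1e-12)
  sp <- associationTest(x, y, "spearman")
  expect_equal(statistic(sp), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
})

test_that("weighted rank correlation behaves at the extremes and has a
           centred permutation null", {
  expect_equal(statistic(associationTest(1:6, (1:6)^3, "weighted_rank")), 1)
  # reversal: evaluate the published formula at the reversing permutation
  expect_equal(statistic(associationTest(1:6, 6:1, "weighted_rank")), -1)
  # exhaustive enumeration over all 24 permutations of n = 4 ranks
  P <- allPerms(4)
  vals <- apply(P, 1, function(s)
    statistic(associationTest(1:4, as.numeric(s), "weighted_rank")))
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  # the normal-approximation variance equals the exact enumeration variance
  z <- statistic(associationTest(1:4, c(2, 1, 4, 3), "weighted_rank"))
  p <- pValue(associationTest(1:4, c(2, 1, 4, 3), "weighted_rank"))
  enumVar <- mean(vals^2)
  expect_equal(p, 2 * pnorm(-abs(z) / sqrt(enumVar)), tolerance = 1e-12)
})

test_that("Hoeffding's D is exactly 1 on monotone data and centred under
           permutation", {
  expect_equal(statistic(associationTest(1:5, 1:5, "hoeffding")), 1)
  expect_equal(statistic(associationTest(1:5, 5:1, "hoeffding")), 1)
  P <- allPerms(5)
  vals <- apply(P, 1, function(s)
    statistic(associationTest(1:5, as.numeric(s), "hoeffding")))
  expect_equal(mean(vals), 0, tolerance = 1e-12)
  # the bound-based p uses the enumeration-verified null variance
  varD <- mean(vals^2)
  expect_equal(varD, 2 * (25 + 25 - 32) / (9 * 5 * 4 * 2 * 1),
               tolerance = 1e-12)
  d <- associationTest(1:5, 1:5, "hoeffding")
  expect_equal(pValue(d), min(1, varD / statistic(d)^2), tolerance = 1e-12)
  # permutation p is available and calibrated to the add-one convention
  dp <- associationTest(1:6, c(2, 1, 4, 3, 6, 5), "hoeffding",
                        hoeffdingP = "permutation", nPerm = 199, seed = 3)
  expect_gte(pValue(dp), 1 / 200)
})

test_that("distance covariance matches direct double-centering and handles
           degenerate input", {
  x <- c(0, 1, 2, 4); y <- c(1, 0, 3, 2)
  d <- associationTest(x, y, "dcov", nPerm = 99, seed = 1)
  expect_equal(statistic(d), oracleDcov2(x, y), tolerance = 1e-12)
  expect_equal(statistic(associationTest(rep(2, 5), 1:5, "dcov",
                                         nPerm = 99, seed = 1)), 0)
  expect_error(associationTest(x, y, "dcov", nPerm = 50, seed = 1),
               class = "configurationError")
  expect_error(associationTest(x, y, "dcov", nPerm = 999),
               class = "configurationError")
})

test_that("Theil-Sen fits exact lines and resists a single outlier", {
  fit <- associationTest(c(0, 1, 2, 3), c(1, 3, 5, 7), "theil_sen")
  expect_equal(statistic(fit), 2)
  expect_equal(fit@extras$intercept, 1)
  # all 10 pairwise slopes of (0,0),(1,1),(2,2),(3,3),(4,0): median is 1
  out <- associationTest(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 0), "theil_sen")
  expect_equal(statistic(out), 1)
  expect_error(associationTest(rep(1, 5), 1:5, "theil_sen"),
               class = "degenerateInputError")
  # regression, not correlation: no reciprocal symmetry in general
  a <- c(1, 2, 4, 8); b <- c(3, 1, 4, 9)
  s1 <- statistic(associationTest(a, b, "theil_sen"))
  s2 <- statistic(associationTest(b, a, "theil_sen"))
  expect_false(isTRUE(all.equal(s1, 1 / s2)))
})

test_that("rank Theil-Sen is Theil-Sen on ranks and is monotone invariant", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    a <- associationTest(x, y, "rank_theil_sen")
    b <- associationTest(rankTransform(x), rankTransform(y), "theil_sen")
    expect_equal(statistic(a), statistic(b))
    expect_equal(pValue(a), pValue(b))
  }
  x <- sort(rnorm(10)); y <- sort(rnorm(10))
  expect_equal(statistic(associationTest(x, y, "rank_theil_sen")), 1)
})

test_that("symmetric measures are exactly symmetric in their arguments", {
  set.seed(5)
  x <- rnorm(18); y <- x + rnorm(18)
  for (m in c("pearson", "spearman", "kendall", "weighted_rank",
              "hoeffding")) {
    expect_equal(statistic(associationTest(x, y, m)),
                 statistic(associationTest(y, x, m)), info = m)
    expect_equal(pValue(associationTest(x, y, m)),
                 pValue(associationTest(y, x, m)), info = m)
  }
  d1 <- associationTest(x, y, "dcov", nPerm = 199, seed = 4)
  d2 <- associationTest(y, x, "dcov", nPerm = 199, seed = 4)
  expect_equal(statistic(d1), statistic(d2))
  expect_equal(pValue(d1), pValue(d2))
})

test_that("statistics stay within their documented ranges", {
  set.seed(6)
  for (i in 1:25) {
    x <- rnorm(12); y <- if (i %% 2) rnorm(12) else x^3 + rnorm(12, sd = .2)
    for (m in c("pearson", "spearman", "kendall", "weighted_rank"))
      expect_lte(abs(statistic(associationTest(x, y, m))), 1)
    D <- statistic(associationTest(x, y, "hoeffding"))
    expect_gte(D, -0.5); expect_lte(D, 1)
    expect_gte(statistic(associationTest(x, y, "dcov", nPerm = 99,
                                         seed = i)), 0)
  }
})

test_that("degenerate and invalid input raise typed errors, never NaN", {
  const <- rep(3, 6); x <- rnorm(6)
  for (m in c("pearson", "spearman", "kendall", "weighted_rank",
              "hoeffding"))
    expect_error(associationTest(const, x, m),
                 class = "degenerateInputError")
  expect_error(associationTest(1:3, 1:4, "pearson"),
               class = "invalidInputError")
  expect_error(associationTest(1:3, 1:3, "pearson"),
               class = "invalidInputError")          # n below minimum
  expect_error(associationTest(1:4, 1:4, "hoeffding"),
               class = "invalidInputError")          # n < 5
  expect_error(associationTest(c(1, 2, NA, 4), 1:4, "pearson"),
               class = "invalidInputError")
})

test_that("Theil-Sen asymptotic breakdown solves the pair-counting
           condition", {
  eps <- theilSenBreakdown()
  expect_equal(eps, 1 - 1 / sqrt(2), tolerance = 1e-9)
  # the condition itself: contaminated pairs are exactly half of all pairs
  expect_equal(1 - (1 - eps)^2, 0.5, tolerance = 1e-9)
})
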