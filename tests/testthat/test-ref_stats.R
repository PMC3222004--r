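test_that("robust interval degenerates gracefully on constant samples", {
  expect_warning(ri <- robustReferenceInterval(rep(885, 45)),
                 "identical")
  expect_equal(c(ri@lower, ri@upper), c(885, 885))
})

test_that("robust interval is affine-equivariant", {
  set.seed(77)
  x <- rnorm(60, 885, 150)
  ri <- robustReferenceInterval(x)
  a <- 2.5; b <- -40
  ri2 <- robustReferenceInterval(a * x + b)
  expect_equal(ri2@lower, a * ri@lower + b, tolerance = 1e-6)
  expect_equal(ri2@upper, a * ri@upper + b, tolerance = 1e-6)
})

test_that("robust limits approach the normal quantiles at large n", {
  set.seed(1)
  x <- rnorm(10000)
  ri <- robustReferenceInterval(x)
  expect_lt(abs(ri@lower - (-1.96)), 0.05)
  expect_lt(abs(ri@upper - 1.96), 0.05)
})

test_that("robust limits resist a wild outlier; parametric limits do not", {
  set.seed(8)
  x <- rnorm(74, 885, 150)
  ri0 <- robustReferenceInterval(x)
  xBad <- c(x[-1], 1e7)
  riBad <- robustReferenceInterval(xBad)
  # bounded influence: limits move by a bounded (small) amount
  expect_lt(abs(riBad@upper - ri0@upper), 200)
  # the naive mean +/- 1.96 sd interval explodes
  naive <- mean(xBad) + c(-1.96, 1.96) * sd(xBad)
  expect_gt(naive[2], 1e5)
})

test_that("small or invalid robust inputs are refused or flagged", {
  expect_error(robustReferenceInterval(rnorm(10)), "n >= 20")
  expect_warning(robustReferenceInterval(rnorm(25)), "n < 40")
  expect_error(robustReferenceInterval(c(rnorm(30), NA)), "finite")
})

test_that("nonparametric limits follow the documented interpolation", {
  ri <- nonparametricReferenceInterval(1:100)
  expect_equal(c(ri@lower, ri@upper), c(3.475, 97.525))
  riC <- nonparametricReferenceInterval(rep(5, 10))
  expect_equal(c(riC@lower, riC@upper), c(5, 5))
})

test_that("robust and nonparametric limits agree at large n", {
  # both estimators carry sampling noise even at n = 10,000, so the
  # comparison averages the discrepancy over replicates and judges it
  # against 1% of the interval width
  set.seed(2)
  diffs <- replicate(10, {
    x <- rnorm(10000, 885, 150)
    rob <- robustReferenceInterval(x)
    np <- nonparametricReferenceInterval(x)
    c(abs(rob@lower - np@lower), abs(rob@upper - np@upper),
      np@upper - np@lower)
  })
  width <- mean(diffs[3, ])
  expect_lt(mean(diffs[1, ]), 0.01 * width)
  expect_lt(mean(diffs[2, ]), 0.01 * width)
})

test_that("t-based CI of a reported mean matches the t table", {
  ci <- ciOfMean(100, 10, 25)
  expect_equal(unname(ci), c(95.8722, 104.1278), tolerance = 1e-4)
  expect_equal(unname(ciOfMean(850, 0, 30)), c(850, 850))
  # large-n half width approaches 1.96 sd/sqrt(n)
  ci2 <- ciOfMean(0, 1, 1e6)
  expect_equal(ci2[["upper"]], 1.96 / 1000, tolerance = 1e-3)
  expect_error(ciOfMean(1, 1, 1), "n must be")
})

test_that("CI width shrinks with n and grows with sd", {
  w <- function(sd, n) diff(unname(ciOfMean(0, sd, n)))
  ns <- c(5, 10, 40, 160)
  expect_true(all(diff(vapply(ns, function(n) w(10, n),
                              numeric(1))) < 0))
  sds <- c(1, 5, 10, 20)
  expect_true(all(diff(vapply(sds, function(s) w(s, 30),
                              numeric(1))) > 0))
})

test_that("percent Bland-Altman handles identity, scale shift, and sign", {
  b <- c(10, 20, 30, 40)
  ba0 <- blandAltmanPercent(b, b)
  expect_equal(ba0@biasPercent, 0)
  expect_equal(c(ba0@loaLowPercent, ba0@loaHighPercent), c(0, 0))

  ba <- blandAltmanPercent(1.02 * b, b)
  expect_equal(ba@biasPercent, 100 * 0.02 / 1.01, tolerance = 1e-10)
  expect_equal(ba@sdPercent, 0)

  # antisymmetry: swapping methods negates bias and mirrors the limits
  set.seed(4)
  a2 <- b * runif(4, 0.9, 1.1)
  ab <- blandAltmanPercent(a2, b)
  ba2 <- blandAltmanPercent(b, a2)
  expect_equal(ba2@biasPercent, -ab@biasPercent)
  expect_equal(ba2@loaLowPercent, -ab@loaHighPercent)
  expect_equal(ba2@loaHighPercent, -ab@loaLowPercent)

  expect_error(blandAltmanPercent(c(1, -1), c(1, 1)), "positive")
})

test_that("geometric ROI mass is area x thickness x water density", {
  expect_equal(geometricRoiMass(2, 5), 0.99777)
  expect_equal(geometricRoiMass(0, 5), 0)
  expect_equal(geometricRoiMass(10, 10), 9.9777)
  expect_error(geometricRoiMass(-1, 5), "area")
  expect_error(geometricRoiMass(1, 0), "thickness")
})

test_that("blocks explaining no variance are dropped by the 5% rule", {
  set.seed(12)
  n <- 200
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  d$y <- 5 * d$x + rnorm(n)
  d$junk <- rnorm(n)  # orthogonal to y by construction
  r <- hierarchicalRegression(d, "y", list("x", "junk"))
  expect_true(r@blockStats$retained[1])
  expect_false(r@blockStats$retained[2])
  expect_false("junk" %in% r@coefficients$term)
})

test_that("duplicate or collinear predictors are named in the error", {
  d <- data.frame(y = rnorm(30), a = rnorm(30))
  d$b <- 2 * d$a
  expect_error(hierarchicalRegression(d, "y", list("a", "a")),
               "more than one block")
  expect_error(hierarchicalRegression(d, "y", list("a", "b")),
               "collinearity.*b")
})

test_that("sex enters the regression dummy-coded with male = 0", {
  d <- makeReferenceCohort(n = 60, family = "gaussian", seed = 5)
  r <- hierarchicalRegression(d, "m_lung_g", list("height_cm", "sex"),
                              retentionThreshold = 0)
  expect_true("sexfemale" %in% r@coefficients$term)
  # recoding by hand reproduces the same estimate
  d$female <- as.integer(d$sex == "female")
  r2 <- hierarchicalRegression(d, "m_lung_g",
                               list("height_cm", "female"),
                               retentionThreshold = 0)
  expect_equal(
    r@coefficients$estimate[r@coefficients$term == "sexfemale"],
    r2@coefficients$estimate[r2@coefficients$term == "female"],
    tolerance = 1e-10)
})

test_that("two-group comparisons use Mann-Whitney with sane extremes", {
  dSame <- data.frame(v = rep(c(1, 2, 3), 2),
                      g = rep(c("a", "b"), each = 3))
  same <- compareGroups(dSame, "v", "g")
  expect_equal(same$test, "mann-whitney")
  expect_gt(same$p.value, 0.99)

  dSep <- data.frame(v = c(1:5, 11:15), g = rep(c("a", "b"), each = 5))
  sep <- compareGroups(dSep, "v", "g")
  expect_equal(sep$statistic, 0)
  expect_lt(sep$p.value, 0.05)

  d3 <- data.frame(v = rnorm(30), g = rep(c("a", "b", "c"), 10))
  expect_equal(compareGroups(d3, "v", "g")$test, "kruskal-wallis")
})

test_that("the rank test holds its nominal size under the null", {
  set.seed(99)
  rej <- mean(replicate(500, {
    d <- data.frame(v = rnorm(40), g = rep(c("a", "b"), each = 20))
    compareGroups(d, "v", "g")$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
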