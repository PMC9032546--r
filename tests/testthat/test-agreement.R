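test_that("through-origin slope and R^2 follow their closed forms", {
  expect_equal(regressThroughOrigin(y = c(1, 2, 3), x = c(1, 2, 3))$k, 1)
  expect_equal(regressThroughOrigin(y = c(1, 2, 3), x = c(1, 2, 3))$rSquared, 1)
  r <- regressThroughOrigin(y = 0.5 * c(2, 5, 9), x = c(2, 5, 9))
  expect_equal(r$k, 0.5)
  expect_equal(r$rSquared, 1)
  # hand-checkable: k = (1.1 + 3.8 + 9.6) / 14 = 14.5/14
  h <- regressThroughOrigin(y = c(1.1, 1.9, 3.2), x = c(1, 2, 3))
  expect_equal(h$k, 14.5 / 14)
  expect_error(regressThroughOrigin(c(1, 2), c(1, 2)), "at least 3")
  expect_error(regressThroughOrigin(c(1, 2, 3), c(0, 0, 0)), "zero")
})

test_that("uncentered R^2 agrees with the no-intercept lm convention", {
  set.seed(20)
  x <- runif(23, 0.1, 0.5)
  y <- 0.97 * x + rnorm(23, 0, 0.02)
  r <- regressThroughOrigin(y, x)
  fit <- lm(y ~ 0 + x)
  expect_equal(r$k, unname(coef(fit)))
  expect_equal(r$rSquared, summary(fit)$r.squared)
  expect_equal(r$pearsonR, unname(cor(x, y)))
})

test_that("through-origin slope is scale-equivariant", {
  set.seed(21)
  x <- runif(15, 0.5, 2)
  y <- 0.8 * x + rnorm(15, 0, 0.1)
  k0 <- regressThroughOrigin(y, x)$k
  expect_equal(regressThroughOrigin(3 * y, x)$k, 3 * k0)
  expect_equal(regressThroughOrigin(y, 2 * x)$k, k0 / 2)
})

test_that("duration selection picks the smallest qualifying window", {
  Is <- seq(12, 70, by = 2)
  allGood <- data.frame(I = Is, k = 1, rSquared = 1)
  expect_identical(selectDuration(allGood)$optimalI, 12)

  lowSlope <- data.frame(I = Is, k = 0.9, rSquared = 1)
  sel <- selectDuration(lowSlope)
  expect_true(is.na(sel$optimalI))
  expect_false(sel$qualified)

  mixed <- data.frame(I = Is, k = ifelse(Is >= 28, 0.96, 0.9),
                      rSquared = ifelse(Is >= 18, 0.995, 0.95))
  expect_identical(selectDuration(mixed)$optimalI, 28)
  expect_error(selectDuration(data.frame(I = numeric(0), k = numeric(0),
                                         rSquared = numeric(0))), "empty")
})

test_that("raising a selection threshold never selects a smaller window", {
  set.seed(22)
  for (rep in 1:20) {
    tab <- data.frame(I = seq(12, 70, by = 2),
                      k = runif(30, 0.9, 1.02),
                      rSquared = runif(30, 0.97, 1))
    base <- selectDuration(tab)$optimalI
    higher <- selectDuration(tab, r2Threshold = 0.995,
                             slopeThreshold = 0.97)$optimalI
    if (!is.na(base) && !is.na(higher)) expect_gte(higher, base)
    if (is.na(base)) expect_true(is.na(higher))
  }
})

test_that("Bland-Altman limits are bias +/- 1.96 SD and behave degenerately", {
  a <- c(1, 2, 3, 4)
  ba <- blandAltman(a, a)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loaLow, 0)
  expect_equal(ba$loaHigh, 0)
  expect_equal(ba$loaHigh - ba$loaLow, 2 * 1.96 * ba$sdDiff)
  expect_error(blandAltman(c(1, 2), c(1, 2)), "at least 3")
})

test_that("published bias and error reproduce the published limits", {
  # differences built to have mean -0.0052 and SD 0.0105 exactly
  z <- as.numeric(scale(1:23))
  d <- -0.0052 + 0.0105 * z
  ba <- blandAltman(d, rep(0, 23))
  expect_equal(ba$bias, -0.0052)
  expect_equal(ba$sdDiff, 0.0105)
  expect_equal(ba$loaLow, -0.02578)
  expect_equal(ba$loaHigh, 0.01538)
  # agrees with the printed limits (-0.0259, 0.0154) within rounding
  expect_lt(abs(ba$loaLow - (-0.0259)), 5e-4)
  expect_lt(abs(ba$loaHigh - 0.0154), 5e-4)
})

test_that("alternating differences give the sample-SD closed form", {
  cst <- 0.3
  d <- rep(c(cst, -cst), 6)
  ba <- blandAltman(d, rep(0, 12))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loaHigh, 1.96 * cst * sqrt(12 / 11))
})

test_that("Bland-Altman is antisymmetric in its arguments", {
  set.seed(23)
  a <- rnorm(10)
  b <- rnorm(10)
  ab <- blandAltman(a, b)
  ba <- blandAltman(b, a)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loaLow, -ba$loaHigh)
  expect_equal(ab$loaHigh, -ba$loaLow)
})

test_that("paired condition comparisons handle identical and degenerate input", {
  x <- c(1, 2, 3, 4, 5)
  t0 <- compareConditions(x, x, test = "paired_t")
  expect_equal(t0$statistic, 0)
  expect_equal(t0$pValue, 1)
  expect_error(compareConditions(x, x, test = "wilcoxon"), "degenerate pairs")
})

test_that("exact Wilcoxon p-values match the sign-enumeration oracle", {
  # one non-zero difference among ten pairs
  box <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10.4)
  stool <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  res <- compareConditions(box, stool, test = "wilcoxon")
  expect_equal(res$pValue, signedRankEnumerationP(box - stool))
  # general small samples with distinct |d|
  for (s in 1:5) {
    set.seed(30 + s)
    d <- round(rnorm(8), 3)
    d <- d[d != 0]
    while (anyDuplicated(abs(d))) d <- d + seq_along(d) * 1e-4
    stool <- rnorm(length(d))
    res <- compareConditions(stool + d, stool, test = "wilcoxon")
    expect_equal(res$pValue, signedRankEnumerationP(d))
  }
})

test_that("cross-condition correlation matches Pearson anchors", {
  x <- c(0.1, 0.2, 0.35, 0.4, 0.55)
  expect_equal(crossConditionCorrelation(x, x)$r, 1)
  a <- c(1, -1, 1, -1)
  b <- c(1, 1, -1, -1)   # zero-mean and orthogonal to a
  expect_lt(abs(crossConditionCorrelation(a, b)$r), 1e-12)
})

test_that("planted through-origin slopes are recovered within 3 SE", {
  kStar <- 0.93
  hits <- 0L
  for (s in 1:50) {
    set.seed(1200 + s)
    x <- rlnorm(23, log(0.23), 0.3)            # SampEn50-like spread
    y <- kStar * x + rnorm(23, 0, 0.015)
    r <- regressThroughOrigin(y, x)
    se <- sqrt(sum((y - r$k * x)^2) / (r$n - 1) / sum(x^2))
    if (abs(r$k - kStar) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})
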