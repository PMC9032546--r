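test_that("perfectly regular series have zero entropy", {
  # constant series: every template pair matches at both lengths
  resConst <- sampEn(rep(3.7, 300), m = 2, r = 0.1, rMode = "absolute")
  cts <- matchCounts(resConst)
  expect_gt(cts["B"], 0)
  expect_equal(cts[["A"]], cts[["B"]])
  expect_equal(sampEnValue(resConst), 0)

  # strictly alternating series: every m-match extends to an (m+1)-match
  resAlt <- sampEn(rep(c(0, 1), 150), m = 2, r = 0.1, rMode = "absolute")
  expect_equal(sampEnValue(resAlt), 0)
  expect_false(resAlt@undefined)
})

test_that("degenerate inputs are rejected or flagged, not mis-valued", {
  expect_error(sampEn(rnorm(150)), "floor")
  expect_error(sampEn(rep(1, 300), r = 0.2, rMode = "relative"),
               "degenerate constant series")
  # strictly increasing integers, tolerance below the step: no matches
  res <- sampEn(as.numeric(1:300), m = 2, r = 0.1, rMode = "absolute")
  expect_true(res@undefined)
  expect_true(is.na(sampEnValue(res)))
  expect_identical(matchCounts(res)[["B"]], 0)
})

test_that("production counts equal the exhaustive oracle on varied series", {
  set.seed(42)
  cases <- data.frame(
    n = sample(200:1000, 25, replace = TRUE),
    kind = rep(c("white", "ar1", "periodic"), length.out = 25),
    seed = sample.int(1e6, 25)
  )
  for (i in seq_len(nrow(cases))) {
    x <- switch(cases$kind[i],
      white = { set.seed(cases$seed[i]); rnorm(cases$n[i]) },
      ar1 = ar1Series(cases$n[i], phi = 0.8, seed = cases$seed[i]),
      periodic = {
        set.seed(cases$seed[i])
        sin(2 * pi * seq_len(cases$n[i]) / 50) + rnorm(cases$n[i], 0, 0.3)
      })
    for (m in c(1, 2, 3)) {
      prod <- sampEn(x, m = m, r = 0.2)
      orac <- sampEnOracle(x, m = m, r = 0.2)
      expect_identical(matchCounts(prod), matchCounts(orac))
      expect_identical(sampEnValue(prod), sampEnValue(orac))
    }
  }
})

test_that("a frozen AR(1) fixture agrees with the oracle bit-exactly", {
  x <- ar1Series(250, phi = 0.9, sd = 2, seed = 123)
  prod <- sampEn(x, m = 2, r = 0.2, rMode = "relative")
  orac <- sampEnOracle(x, m = 2, r = 0.2, rMode = "relative")
  expect_identical(matchCounts(prod), matchCounts(orac))
  expect_false(prod@undefined)
  expect_true(prod@A <= prod@B)
})

test_that("oracle invariances: time reversal and exact scale equivariance", {
  x <- ar1Series(300, seed = 7)
  a <- sampEnOracle(x, m = 2, r = 0.3, rMode = "absolute")
  b <- sampEnOracle(rev(x), m = 2, r = 0.3, rMode = "absolute")
  expect_identical(matchCounts(a)[["A"]], matchCounts(b)[["A"]])
  expect_equal(sampEnValue(a), sampEnValue(b), tolerance = 5e-3)
  # power-of-two scaling is exact in floating point
  c <- sampEnOracle(4 * x, m = 2, r = 4 * 0.3, rMode = "absolute")
  expect_identical(matchCounts(a), matchCounts(c))
})

test_that("SampEn is non-increasing in the absolute tolerance", {
  for (seed in 1:5) {
    x <- ar1Series(400, phi = 0.6, seed = seed)
    rs <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
    vals <- vapply(rs, function(r) {
      res <- sampEn(x, m = 2, r = r, rMode = "absolute")
      if (res@undefined) Inf else sampEnValue(res)
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("SampEn is invariant to shift, negation, reversal and affine rescaling", {
  x <- ar1Series(350, phi = 0.7, seed = 11)
  ref <- sampEn(x, m = 2, r = 0.2, rMode = "relative")
  expect_identical(matchCounts(sampEn(x + 17.3, m = 2, r = 0.2)),
                   matchCounts(ref))
  expect_identical(matchCounts(sampEn(-x, m = 2, r = 0.2)),
                   matchCounts(ref))
  # reversal: A is exactly invariant (its m+1 templates map onto themselves);
  # B's shared counting range i, j <= N - m excludes one boundary template,
  # which reversal swaps for the one at the other end, so B may move by a
  # few boundary pairs and the entropy by a correspondingly tiny amount
  revd <- sampEn(rev(x), m = 2, r = 0.2)
  expect_identical(matchCounts(revd)[["A"]], matchCounts(ref)[["A"]])
  expect_lte(abs(matchCounts(revd)[["B"]] - matchCounts(ref)[["B"]]),
             2 * 2 * (length(x) - 2))
  expect_equal(sampEnValue(revd), sampEnValue(ref), tolerance = 5e-3)
  # relative mode: affine rescaling leaves the result unchanged
  expect_equal(sampEnValue(sampEn(2.5 * x - 4, m = 2, r = 0.2)),
               sampEnValue(ref), tolerance = 1e-9)
})

test_that("the tolerance is resolved from the population SD", {
  x <- ar1Series(260, seed = 5)
  res <- sampEn(x, m = 2, r = 0.2, rMode = "relative")
  sdPop <- sqrt(mean((x - mean(x))^2))
  expect_equal(res@rAbs, 0.2 * sdPop)
  # equivalent absolute call gives identical counts
  resAbs <- sampEn(x, m = 2, r = 0.2 * sdPop, rMode = "absolute")
  expect_identical(matchCounts(res), matchCounts(resAbs))
})
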