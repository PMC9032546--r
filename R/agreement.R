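#' Through-origin regression y = k x
#'
#' Fits the no-intercept model `y = k x` with `k = sum(xy) / sum(x^2)` and
#' reports the coefficient of determination under the uncentered convention
#' standard for regression through the origin,
#' `R^2 = 1 - sum((y - kx)^2) / sum(y^2)`; the centered alternative (total
#' sum of squares about the mean of y), which can leave `[0, 1]` for
#' through-origin fits, is available for sensitivity checks.  The Pearson
#' correlation between x and y and its two-sided p-value are reported
#' alongside.
#'
#' @param y,x numeric vectors of equal length n >= 3 (e.g. partial-window
#'   SampEn and full-series SampEn across participants).
#' @param r2 `"uncentered"` (default) or `"centered"`.
#' @return list with elements `k`, `rSquared`, `pearsonR`, `pValue`, `n`.
#' @examples
#' regressThroughOrigin(y = c(1.1, 1.9, 3.2), x = c(1, 2, 3))
#' @export
regressThroughOrigin <- function(y, x, r2 = c("uncentered", "centered")) {
  r2 <- match.arg(r2)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 complete pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("x is identically zero")
  k <- sum(x * y) / sxx
  rss <- sum((y - k * x)^2)
  tss <- if (r2 == "uncentered") sum(y^2) else sum((y - mean(y))^2)
  rSquared <- if (tss == 0) NA_real_ else 1 - rss / tss
  ct <- suppressWarnings(stats::cor.test(x, y))
  list(k = k, rSquared = rSquared,
       pearsonR = unname(ct$estimate), pValue = ct$p.value, n = n)
}

#' Select the shortest test duration with near-perfect SampEn agreement
#'
#' Given a per-window regression table (one through-origin fit of partial
#' SampEn on full-series SampEn per window end I), returns the smallest I
#' whose fit has `R^2` above `r2Threshold` and slope k above
#' `slopeThreshold` — the shortest window that predicts the full-test
#' entropy to the required degree.  When no window qualifies the selection
#' carries `optimalI = NA` and `qualified = FALSE`.
#'
#' @param table data.frame with columns `I`, `k`, `rSquared` (one row per
#'   window, e.g. built from [regressThroughOrigin()] over
#'   [sampEnPartials()] output).
#' @param r2Threshold minimum coefficient of determination (default 0.99,
#'   strict inequality).
#' @param slopeThreshold minimum slope (default 0.95, strict inequality).
#' @return list with `optimalI` (seconds, `NA` when none qualifies),
#'   `qualified` flag, the thresholds, and the input table.
#' @export
selectDuration <- function(table, r2Threshold = 0.99, slopeThreshold = 0.95) {
  if (!nrow(table)) stop("empty regression table")
  need <- c("I", "k", "rSquared")
  if (!all(need %in% names(table))) {
    stop("table must have columns I, k, rSquared")
  }
  tab <- table[order(table$I), , drop = FALSE]
  ok <- !is.na(tab$rSquared) & !is.na(tab$k) &
    tab$rSquared > r2Threshold & tab$k > slopeThreshold
  optimalI <- if (any(ok)) tab$I[which(ok)[1]] else NA_real_
  list(optimalI = optimalI, qualified = any(ok),
       r2Threshold = r2Threshold, slopeThreshold = slopeThreshold,
       table = tab)
}

#' Bland-Altman agreement between two paired measurements
#'
#' Differences `d = a - b`; bias is their mean, and the 95% limits of
#' agreement are `bias +/- 1.96 * SD(d)` (sample SD, divisor n - 1) — the
#' interval expected to contain 95% of the differences.  The per-pair
#' (mean, difference) table used for the usual plot is returned as well.
#'
#' @param a,b numeric vectors of equal length n >= 3 (e.g. full-series and
#'   partial-window SampEn across participants).
#' @return list with `bias`, `sdDiff`, `loaLow`, `loaHigh`, `n`, and the
#'   data.frame `pairs` with columns `mean` and `difference`.
#' @examples
#' set.seed(1)
#' a <- rnorm(20); b <- a + rnorm(20, 0, 0.01)
#' blandAltman(a, b)$bias
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- a - b
  bias <- mean(d)
  sdDiff <- stats::sd(d)
  list(bias = bias, sdDiff = sdDiff,
       loaLow = bias - 1.96 * sdDiff, loaHigh = bias + 1.96 * sdDiff,
       n = n,
       pairs = data.frame(mean = (a + b) / 2, difference = d))
}

#' Paired comparison between the two test conditions
#'
#' Wilcoxon signed-rank test (exact null for n <= 25 without ties or zero
#' differences, normal approximation with continuity and tie correction
#' otherwise) or paired t-test, two-sided.
#'
#' @param box,stool paired numeric vectors of equal length n >= 5.
#' @param test `"wilcoxon"` (default) or `"paired_t"`.
#' @return list with `statistic`, `pValue`, `n`, `test`.
#' @export
compareConditions <- function(box, stool, test = c("wilcoxon", "paired_t")) {
  test <- match.arg(test)
  if (length(box) != length(stool)) stop("paired samples must have equal length")
  ok <- is.finite(box) & is.finite(stool)
  box <- box[ok]
  stool <- stool[ok]
  n <- length(box)
  if (n < 5L) stop("need at least 5 complete pairs")
  d <- box - stool
  if (test == "wilcoxon") {
    if (all(d == 0)) stop("degenerate pairs: all differences are zero")
    dNZ <- d[d != 0]
    exactOK <- n <= 25L && !anyDuplicated(abs(dNZ)) && all(d != 0)
    ht <- suppressWarnings(
      stats::wilcox.test(box, stool, paired = TRUE, exact = exactOK,
                         correct = !exactOK))
  } else {
    if (all(d == 0)) {
      # identical samples: no evidence of any difference
      return(list(statistic = 0, pValue = 1, n = n, test = test))
    }
    ht <- stats::t.test(box, stool, paired = TRUE)
  }
  list(statistic = unname(ht$statistic), pValue = ht$p.value, n = n,
       test = test)
}

#' Pearson correlation of a quantity across the two conditions
#'
#' Correlates per-participant values from the box-like test with those from
#' the stool-like test (e.g. SampEn of one channel), reporting Pearson r and
#' its two-sided p-value.
#'
#' @param box,stool paired numeric vectors, equal length n >= 3.
#' @return list with `r`, `pValue`, `n`.
#' @export
crossConditionCorrelation <- function(box, stool) {
  if (length(box) != length(stool)) stop("paired samples must have equal length")
  ok <- is.finite(box) & is.finite(stool)
  box <- box[ok]
  stool <- stool[ok]
  if (length(box) < 3L) stop("need at least 3 complete pairs")
  ct <- suppressWarnings(stats::cor.test(box, stool))
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(box))
}
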