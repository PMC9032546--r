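resolveSampEnInput <- function(x) {
  if (is(x, "TrimmedSeries")) trimmedValues(x) else as.numeric(x)
}

validateSampEnArgs <- function(x, m, r, rMode, nFloor) {
  n <- length(x)
  if (n < nFloor) {
    stop("series length ", n, " is below the floor of ", nFloor,
         " samples required for a stable SampEn")
  }
  if (n <= m + 1L) stop("series must be longer than m + 1")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  if (m < 1L) stop("embedding dimension m must be >= 1")
  rMode <- match.arg(rMode, c("relative", "absolute"))
  if (rMode == "relative") {
    if (r <= 0) stop("relative tolerance r must be > 0")
    sdx <- popSd(x)
    if (sdx == 0) stop("degenerate constant series under relative tolerance")
    rAbs <- r * sdx
  } else {
    if (r < 0) stop("absolute tolerance r must be >= 0")
    rAbs <- r
  }
  list(n = n, rMode = rMode, rAbs = rAbs)
}

makeSampEnResult <- function(counts, n, m, r, rMode, rAbs) {
  A <- counts$A
  B <- counts$B
  undefined <- (A == 0 || B == 0)
  new("SampEnResult",
      sampen = if (undefined) NA_real_ else -log(A / B),
      A = A, B = B,
      nTemplates = as.integer(counts$nTemplates),
      n = as.integer(n), m = as.integer(m),
      rMode = rMode, rValue = r, rAbs = rAbs,
      undefined = undefined)
}

#' Sample Entropy of a finite series
#'
#' SampEn(m, r, N) = -ln(A/B), where B is the number of ordered template
#' pairs (i, j), i != j, whose length-m templates
#' `u_i = (x_i, ..., x_{i+m-1})` match within Chebyshev distance r
#' (inclusive), and A is the same count at length m+1.  Both counts run over
#' the shared template range `i, j <= N - m`, so `A <= B` always and a lower
#' SampEn means a more regular, more predictable series.
#'
#' In relative mode the tolerance is `r` times the population SD (divisor N)
#' of the series, the convention under which SampEn is invariant to affine
#' rescaling.  The exact pair counts are computed by an exhaustive double
#' loop in compiled code; no approximate neighbour search is involved.
#'
#' @param x numeric series or a [TrimmedSeries-class].
#' @param m embedding dimension (default 2).
#' @param r tolerance (default 0.2); a multiple of the series SD in
#'   `"relative"` mode, in the units of `x` in `"absolute"` mode.
#' @param rMode `"relative"` (default) or `"absolute"`.
#' @param nFloor minimum series length (default 200, below which SampEn of
#'   physiological series is not considered stable).
#' @return a [SampEnResult-class].  When no template pairs match at length m
#'   (or m+1), the result carries the `undefined` flag instead of an error,
#'   so cohort-level code can skip such series.
#' @examples
#' set.seed(1)
#' sampEn(rnorm(300))
#' @seealso [sampEnOracle()] for the independent verification twin.
#' @export
sampEn <- function(x, m = 2L, r = 0.2, rMode = c("relative", "absolute"),
                   nFloor = 200L) {
  x <- resolveSampEnInput(x)
  m <- as.integer(m)
  v <- validateSampEnArgs(x, m, r, rMode, nFloor)
  counts <- .sampenCounts(x, m, v$rAbs)
  makeSampEnResult(counts, v$n, m, r, v$rMode, v$rAbs)
}

#' Exhaustive-count Sample Entropy oracle
#'
#' Verification twin of [sampEn()]: a direct transcription of the SampEn
#' definition in plain R, enumerating all template pairs exhaustively.  It
#' shares no counting code with the production path and exists so that the
#' two can be compared bit-exactly on the match counts A and B.
#'
#' @inheritParams sampEn
#' @return a [SampEnResult-class].
#' @export
sampEnOracle <- function(x, m = 2L, r = 0.2,
                         rMode = c("relative", "absolute"), nFloor = 200L) {
  x <- resolveSampEnInput(x)
  m <- as.integer(m)
  v <- validateSampEnArgs(x, m, r, rMode, nFloor)
  nt <- v$n - m
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    cheb <- abs(x[i] - x[js])
    for (k in seq_len(m - 1L)) {
      cheb <- pmax(cheb, abs(x[i + k] - x[js + k]))
    }
    mMatch <- cheb <= v$rAbs
    B <- B + 2 * sum(mMatch)
    if (any(mMatch)) {
      jm <- js[mMatch]
      A <- A + 2 * sum(abs(x[i + m] - x[jm + m]) <= v$rAbs)
    }
  }
  makeSampEnResult(list(A = A, B = B, nTemplates = nt),
                   v$n, m, r, v$rMode, v$rAbs)
}
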