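#' SampEn of the full trimmed test span
#'
#' The entropy of the complete series spanning all bending cycles (the
#' "SampEn50" of a 50-cycle test).
#'
#' @param trimmed a [TrimmedSeries-class].
#' @inheritParams sampEn
#' @return a [SampEnResult-class].
#' @export
sampEn50 <- function(trimmed, m = 2L, r = 0.2,
                     rMode = c("relative", "absolute"), nFloor = 200L) {
  sampEn(trimmed, m = m, r = r, rMode = rMode, nFloor = nFloor)
}

#' Partial SampEn on growing windows
#'
#' Computes SampEn on the partial series from `tStart` seconds to I seconds
#' after the trim start, for I = `tStart + step`, `tStart + 2 step`, ...,
#' `tEnd` (default 12, 14, ..., 70 s).  The first 10 s are skipped to
#' exclude habituation effects, and each 2 s step adds exactly
#' `step * samplingRate` samples (200 at 100 Hz), so every window holds an
#' exact sample count: window I covers samples `[tStart * fs, I * fs)`
#' (0-based, half-open, relative to the trim start) and contains
#' `(I - tStart) * fs` samples.
#'
#' In relative mode the tolerance is resolved per window (each window uses
#' its own SD, `rScope = "window"`); `rScope = "full"` resolves it once from
#' the full trimmed series instead.
#'
#' If the series is shorter than `tEnd` seconds the table is truncated at
#' the last complete window with a warning; a series shorter than
#' `tStart + step` seconds is an error.
#'
#' @param trimmed a [TrimmedSeries-class].
#' @inheritParams sampEn
#' @param tStart window origin, seconds after trim start (default 10).
#' @param tEnd last window end, seconds (default 70).
#' @param step window increment, seconds (default 2).
#' @param rScope `"window"` (default) or `"full"`: where the SD behind a
#'   relative tolerance is taken from.
#' @return data.frame with columns `I` (window end, seconds), `sampen`, `A`,
#'   `B`, `n` (samples in the window) and `undefined`; SampEn parameters are
#'   attached as the `"params"` attribute.
#' @examples
#' rec <- simulateRecording(participantParams(nCycles = 20), seed = 3)
#' tr <- segmentTest(rec)
#' head(sampEnPartials(tr$GyrX, tEnd = 30))
#' @export
sampEnPartials <- function(trimmed, m = 2L, r = 0.2,
                           rMode = c("relative", "absolute"),
                           tStart = 10, tEnd = 70, step = 2,
                           rScope = c("window", "full"), nFloor = 200L) {
  stopifnot(is(trimmed, "TrimmedSeries"))
  rMode <- match.arg(rMode)
  rScope <- match.arg(rScope)
  fs <- samplingRate(trimmed)
  v <- trimmedValues(trimmed)
  span <- length(v) / fs
  if (span < tStart + step) {
    stop("trimmed span (", round(span, 2), " s) is shorter than tStart + ",
         "step = ", tStart + step, " s")
  }
  lastI <- tStart + step * floor((min(span, tEnd) - tStart) / step)
  if (lastI < tEnd) {
    warning("trimmed span shorter than ", tEnd,
            " s; truncating the table at I = ", lastI, " s")
  }
  Is <- seq(tStart + step, lastI, by = step)

  rUse <- r
  rModeUse <- rMode
  if (rMode == "relative" && rScope == "full") {
    rUse <- r * popSd(v)
    rModeUse <- "absolute"
  }

  rows <- lapply(Is, function(I) {
    idx <- (round(tStart * fs) + 1L):round(I * fs)
    res <- sampEn(v[idx], m = m, r = rUse, rMode = rModeUse, nFloor = nFloor)
    data.frame(I = I, sampen = res@sampen, A = res@A, B = res@B,
               n = length(idx), undefined = res@undefined)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(m = m, r = r, rMode = rMode, rScope = rScope,
                              tStart = tStart, step = step)
  out
}
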