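#' Trim a recording to the bending-cycle test span
#'
#' Localises the span covering the bending-and-return cycles and returns
#' every channel restricted to it.  The protocol asks the participant to
#' perform a left-right rotation (a clear pulse on the marker channel) just
#' before starting the cycles, so the start of the test can be found
#' automatically: the trim starts at the sample nearest to zero on GyrX
#' after the marker ends and before the first cycle's angular velocity
#' exceeds a launch threshold (10% of the post-marker GyrX peak), and ends
#' at the last sample nearest to zero on GyrX after the final cycle.  The
#' same half-open span `[start, end)` (0-based) is applied to all six
#' channels.
#'
#' Threshold crossings (marker detection, cycle launch/landing) are
#' evaluated on a 0.15 s moving-average envelope of the rectified signal so
#' that sensor noise does not trigger false onsets; the nearest-zero search
#' itself runs on the raw samples.
#'
#' With `markerChannel = NULL` the marker search is skipped and only the
#' nearest-zero endpoint rule is applied from the first sample on; this is
#' the mode to use for recordings that are already trimmed (on such input
#' the operation is the identity, making trimming idempotent).
#'
#' @param rec an [IMURecording-class].
#' @param markerChannel channel carrying the left-right rotation marker
#'   (default `"GyrY"`), or `NULL` for pre-trimmed recordings.
#' @param zeroTol tolerance in degrees/s below which a GyrX sample counts as
#'   "at zero" (default 2).
#' @return named list of six [TrimmedSeries-class] objects
#'   (`AccX`, ..., `GyrZ`), all sharing the same span.
#' @examples
#' rec <- simulateRecording(participantParams(nCycles = 10), seed = 2)
#' tr <- segmentTest(rec)
#' tr$GyrX
#' @export
segmentTest <- function(rec, markerChannel = "GyrY", zeroTol = 2) {
  stopifnot(is(rec, "IMURecording"))
  checkPositiveScalar(zeroTol, "zeroTol")
  fs <- samplingRate(rec)
  gx <- channel(rec, "GyrX")
  n <- length(gx)
  smoothWidth <- max(1L, as.integer(round(0.15 * fs)))
  gxEnv <- movingAverage(abs(gx), smoothWidth)

  if (!is.null(markerChannel)) {
    mk <- channel(rec, markerChannel)
    mkEnv <- movingAverage(abs(mk), smoothWidth)
    inMarker <- which(mkEnv > 5 * zeroTol)
    if (!length(inMarker)) stop("marker not detected")
    peak <- max(mkEnv[inMarker])
    # marker end: last crossing of half the marker peak
    markerEnd <- max(which(mkEnv >= 0.5 * peak))
  } else {
    markerEnd <- 1L
  }

  post <- markerEnd:n
  gxPeak <- max(gxEnv[post])
  launch <- 0.1 * gxPeak
  # sustained exceedance only: correlated sensor noise can push the envelope
  # over the threshold briefly, a bending half-cycle keeps it there
  over <- gxEnv[post] >= launch
  runs <- rle(over)
  runEnds <- cumsum(runs$lengths)
  runStarts <- runEnds - runs$lengths + 1L
  minRun <- max(1L, as.integer(round(0.2 * fs)))
  keep <- runs$values & runs$lengths >= minRun
  if (!any(keep)) stop("no bending cycles found after the marker")
  firstOver <- post[runStarts[which(keep)[1]]]
  lastOver <- post[runEnds[which(keep)[sum(keep)]]]

  # start: nearest-to-zero raw sample just before the first cycle launches
  preSpan <- markerEnd:firstOver
  nearZero <- preSpan[abs(gx[preSpan]) <= zeroTol]
  start <- if (length(nearZero)) nearZero[length(nearZero)] else {
    preSpan[which.min(abs(gx[preSpan]))]
  }
  # end: nearest-to-zero raw sample just after the last cycle lands
  postSpan <- lastOver:n
  nearZeroEnd <- postSpan[abs(gx[postSpan]) <= zeroTol]
  endIncl <- if (length(nearZeroEnd)) nearZeroEnd[1] else {
    postSpan[which.min(abs(gx[postSpan]))]
  }

  start0 <- start - 1L                    # 0-based
  end0 <- endIncl                         # half-open: sample endIncl included
  if (end0 - start0 < 200L) {
    stop("fewer than 200 samples between detected start and end")
  }
  sel <- (start0 + 1L):end0
  out <- lapply(IMU_CHANNELS, function(ch) {
    new("TrimmedSeries",
        values = rec@data[sel, ch],
        startIndex = as.integer(start0),
        endIndex = as.integer(end0),
        channel = ch,
        samplingRate = fs)
  })
  names(out) <- IMU_CHANNELS
  out
}

#' Restrict a recording to a trimmed span
#'
#' Returns a new [IMURecording-class] containing only the samples of the
#' half-open span `[start, end)` found by [segmentTest()], with the time
#' axis restarted at zero.
#'
#' @param rec an [IMURecording-class].
#' @param trimmed output of [segmentTest()] (a list of
#'   [TrimmedSeries-class]) or a single [TrimmedSeries-class].
#' @return an [IMURecording-class].
#' @export
trimRecording <- function(rec, trimmed) {
  stopifnot(is(rec, "IMURecording"))
  ts <- if (is(trimmed, "TrimmedSeries")) trimmed else trimmed[[1]]
  sel <- (ts@startIndex + 1L):ts@endIndex
  new("IMURecording",
      data = rec@data[sel, , drop = FALSE],
      time = (seq_along(sel) - 1L) / rec@samplingRate,
      samplingRate = rec@samplingRate,
      meta = c(rec@meta,
               list(trimStart = ts@startIndex, trimEnd = ts@endIndex)))
}
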