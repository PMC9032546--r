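#' @import methods
NULL

IMU_CHANNELS <- c("AccX", "AccY", "AccZ", "GyrX", "GyrY", "GyrZ")

#' IMURecording: six synchronized IMU channels
#'
#' Container for one recording of a repeated trunk bending-and-return test:
#' three accelerometer channels (AccX/AccY/AccZ, units g) and three gyroscope
#' channels (GyrX/GyrY/GyrZ, units degrees/s), sampled on a uniform time grid.
#' As worn on the sacrum, X points left (transverse axis: sagittal-plane
#' rotation appears on GyrX), Y points up and Z points backward.
#'
#' @slot data numeric matrix, one row per sample, columns
#'   `AccX, AccY, AccZ, GyrX, GyrY, GyrZ`.
#' @slot time numeric vector of sample times in seconds, strictly increasing
#'   with uniform step `1/samplingRate`.
#' @slot samplingRate sampling frequency in Hz.
#' @slot meta list of free-form metadata (`participant`, `condition`,
#'   `notes`, simulation ground truth, ...).
#'
#' @seealso [simulateRecording()], [readRecording()], [segmentTest()]
#' @export
setClass("IMURecording",
  representation(
    data = "matrix",
    time = "numeric",
    samplingRate = "numeric",
    meta = "list"
  )
)

setValidity("IMURecording", function(object) {
  d <- object@data
  msgs <- character()
  if (!is.numeric(d) || ncol(d) != 6L ||
      !identical(colnames(d), IMU_CHANNELS)) {
    msgs <- c(msgs, sprintf("data must be a numeric matrix with columns %s",
                            paste(IMU_CHANNELS, collapse = ", ")))
  }
  if (nrow(d) < 2L) msgs <- c(msgs, "recording must contain at least 2 samples")
  if (length(object@time) != nrow(d)) {
    msgs <- c(msgs, "time must have one entry per sample")
  }
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msgs <- c(msgs, "samplingRate must be a single positive number")
  }
  if (any(!is.finite(d))) msgs <- c(msgs, "data contains non-finite values")
  if (length(object@time) >= 2L) {
    dt <- diff(object@time)
    if (any(dt <= 0)) {
      msgs <- c(msgs, "time must be strictly increasing")
    } else {
      jitter <- (max(dt) - min(dt)) / stats::median(dt)
      if (jitter > 0.01) {
        msgs <- c(msgs, sprintf(
          "non-uniform sampling: relative jitter %.3g exceeds 1%%", jitter))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TrimmedSeries: one channel restricted to the test span
#'
#' One kinematic channel cut down to the span covering the bending cycles,
#' together with its provenance in the source recording (0-based, half-open
#' `[startIndex, endIndex)` sample indices).  SampEn needs at least 200
#' samples to be stable on short physiological series, so spans shorter than
#' 200 samples are rejected.
#'
#' @slot values numeric samples in the units of the source channel.
#' @slot startIndex,endIndex 0-based half-open indices into the source
#'   recording.
#' @slot channel channel name, one of `AccX..GyrZ`.
#' @slot samplingRate sampling frequency in Hz.
#'
#' @seealso [segmentTest()], [sampEn()], [integrateGyro()]
#' @export
setClass("TrimmedSeries",
  representation(
    values = "numeric",
    startIndex = "integer",
    endIndex = "integer",
    channel = "character",
    samplingRate = "numeric"
  )
)

setValidity("TrimmedSeries", function(object) {
  msgs <- character()
  n <- length(object@values)
  if (n < 200L) {
    msgs <- c(msgs, "trimmed span must contain at least 200 samples")
  }
  if (any(!is.finite(object@values))) {
    msgs <- c(msgs, "values contain non-finite entries")
  }
  if (object@startIndex < 0L ||
      object@endIndex - object@startIndex != n) {
    msgs <- c(msgs, "indices must satisfy endIndex - startIndex == length(values)")
  }
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0) {
    msgs <- c(msgs, "samplingRate must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' AngleTrace: integrated sagittal-plane trunk angle
#'
#' Trunk pitch angle (degrees) obtained by cumulative trapezoidal integration
#' of the trimmed GyrX channel, with the integration constant fixed so that
#' the trace starts at zero.  When `detrended` is `TRUE` a fitted linear drift
#' (gyroscope bias) has been removed; the trace is re-anchored at zero after
#' detrending so `angle[1] == 0` always holds.
#'
#' @slot angle numeric vector, degrees.
#' @slot samplingRate Hz.
#' @slot detrended logical flag.
#' @slot method integration method tag (`"trapezoid"`).
#'
#' @seealso [integrateGyro()], [detectCycles()]
#' @export
setClass("AngleTrace",
  representation(
    angle = "numeric",
    samplingRate = "numeric",
    detrended = "logical",
    method = "character"
  )
)

setValidity("AngleTrace", function(object) {
  if (length(object@angle) < 2L) return("angle trace too short")
  if (abs(object@angle[1]) > 1e-9) return("angle[1] must be 0")
  TRUE
})

#' CycleAmplitudes: per-cycle angular amplitudes
#'
#' Alternating minima and maxima of an angle trace and the consecutive
#' amplitudes `A_i = max_i - min_i`, one per bending cycle (each minimum is
#' paired with the following maximum).
#'
#' @slot minima,maxima data.frames with columns `index` (1-based sample
#'   index) and `angle` (degrees), alternating in index order.
#' @slot amplitudes numeric vector of per-cycle amplitudes, degrees, all > 0.
#' @slot meanAmplitude mean of `amplitudes`.
#' @slot nCycles number of cycles (length of `amplitudes`).
#'
#' @seealso [detectCycles()]
#' @export
setClass("CycleAmplitudes",
  representation(
    minima = "data.frame",
    maxima = "data.frame",
    amplitudes = "numeric",
    meanAmplitude = "numeric",
    nCycles = "integer"
  )
)

setValidity("CycleAmplitudes", function(object) {
  msgs <- character()
  if (any(object@amplitudes <= 0)) msgs <- c(msgs, "amplitudes must be > 0")
  if (object@nCycles != length(object@amplitudes)) {
    msgs <- c(msgs, "nCycles must equal length(amplitudes)")
  }
  ext <- rbind(cbind(object@minima$index, -1), cbind(object@maxima$index, 1))
  ext <- ext[order(ext[, 1]), , drop = FALSE]
  if (nrow(ext) >= 2L && any(diff(ext[, 2]) == 0)) {
    msgs <- c(msgs, "minima and maxima must alternate in index order")
  }
  if (length(msgs)) msgs else TRUE
})

#' SampEnResult: Sample Entropy with its match counts
#'
#' SampEn = -ln(A/B) where B counts ordered template pairs (self-matches
#' excluded) within tolerance r at embedding length m and A counts the same
#' pairs at length m+1.  When A or B is zero the entropy is undefined
#' (`undefined` flag set, `sampen` is `NA`) rather than infinite, so cohort
#' aggregation can skip such series.
#'
#' @slot sampen entropy in nats, or `NA` when undefined.
#' @slot A,B ordered match-pair counts at lengths m+1 and m.
#' @slot nTemplates number of templates N - m.
#' @slot n series length N.
#' @slot m embedding dimension.
#' @slot rMode `"relative"` (r is a multiple of the series SD) or
#'   `"absolute"`.
#' @slot rValue tolerance as supplied.
#' @slot rAbs tolerance resolved to the units of the series.
#' @slot undefined logical flag.
#'
#' @seealso [sampEn()], [sampEnOracle()]
#' @export
setClass("SampEnResult",
  representation(
    sampen = "numeric",
    A = "numeric",
    B = "numeric",
    nTemplates = "integer",
    n = "integer",
    m = "integer",
    rMode = "character",
    rValue = "numeric",
    rAbs = "numeric",
    undefined = "logical"
  )
)

setValidity("SampEnResult", function(object) {
  msgs <- character()
  if (object@A < 0 || object@B < 0 || object@A > object@B) {
    msgs <- c(msgs, "counts must satisfy 0 <= A <= B")
  }
  if (!object@undefined) {
    expected <- -log(object@A / object@B)
    if (!isTRUE(all.equal(object@sampen, expected))) {
      msgs <- c(msgs, "sampen must equal -ln(A/B)")
    }
  } else if (!is.na(object@sampen)) {
    msgs <- c(msgs, "undefined results must carry sampen = NA")
  }
  if (length(msgs)) msgs else TRUE
})
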