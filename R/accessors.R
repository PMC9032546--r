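#' @describeIn samplingRate sampling rate of a recording
#' @export
setMethod("samplingRate", "IMURecording", function(object) object@samplingRate)

#' @describeIn samplingRate sampling rate of a trimmed series
#' @export
setMethod("samplingRate", "TrimmedSeries", function(object) object@samplingRate)

#' @describeIn samplingRate sampling rate of an angle trace
#' @export
setMethod("samplingRate", "AngleTrace", function(object) object@samplingRate)

#' @describeIn nSamples samples in a recording
#' @export
setMethod("nSamples", "IMURecording", function(object) nrow(object@data))

#' @describeIn nSamples samples in a trimmed series
#' @export
setMethod("nSamples", "TrimmedSeries", function(object) length(object@values))

#' @describeIn duration duration of a recording
#' @export
setMethod("duration", "IMURecording",
          function(object) nSamples(object) / samplingRate(object))

#' @describeIn duration duration of a trimmed series
#' @export
setMethod("duration", "TrimmedSeries",
          function(object) nSamples(object) / samplingRate(object))

#' Channel matrix of a recording
#'
#' @param rec an [IMURecording-class].
#' @return numeric matrix with columns `AccX..GyrZ`.
#' @export
imuChannels <- function(rec) {
  stopifnot(is(rec, "IMURecording"))
  rec@data
}

#' Extract one channel from a recording
#'
#' @param rec an [IMURecording-class].
#' @param name channel name (case-sensitive, one of `AccX..GyrZ`).
#' @return numeric vector.
#' @export
channel <- function(rec, name) {
  stopifnot(is(rec, "IMURecording"))
  if (!name %in% IMU_CHANNELS) {
    stop("unknown channel '", name, "'; expected one of ",
         paste(IMU_CHANNELS, collapse = ", "))
  }
  rec@data[, name]
}

#' Recording metadata
#'
#' @param rec an [IMURecording-class].
#' @return list of metadata.
#' @export
imuMeta <- function(rec) {
  stopifnot(is(rec, "IMURecording"))
  rec@meta
}

#' Time vector of a recording
#'
#' @param rec an [IMURecording-class].
#' @return numeric vector of sample times, seconds.
#' @export
imuTime <- function(rec) {
  stopifnot(is(rec, "IMURecording"))
  rec@time
}

#' Values of a trimmed series
#'
#' @param x a [TrimmedSeries-class].
#' @return numeric vector of samples.
#' @export
trimmedValues <- function(x) {
  stopifnot(is(x, "TrimmedSeries"))
  x@values
}

#' Trim span of a trimmed series
#'
#' @param x a [TrimmedSeries-class].
#' @return integer vector `c(start, end)` — 0-based, half-open indices into
#'   the source recording.
#' @export
trimSpan <- function(x) {
  stopifnot(is(x, "TrimmedSeries"))
  c(start = x@startIndex, end = x@endIndex)
}

#' Channel name of a trimmed series
#'
#' @param x a [TrimmedSeries-class].
#' @return character channel name.
#' @export
channelName <- function(x) {
  stopifnot(is(x, "TrimmedSeries"))
  x@channel
}

#' Angle values of an angle trace
#'
#' @param x an [AngleTrace-class].
#' @return numeric vector, degrees.
#' @export
angleValues <- function(x) {
  stopifnot(is(x, "AngleTrace"))
  x@angle
}

#' Entropy value of a SampEn result
#'
#' @param x a [SampEnResult-class].
#' @return SampEn in nats, `NA` if undefined.
#' @export
sampEnValue <- function(x) {
  stopifnot(is(x, "SampEnResult"))
  x@sampen
}

#' Match counts of a SampEn result
#'
#' @param x a [SampEnResult-class].
#' @return named numeric vector with elements `A` (length m+1 matches), `B`
#'   (length m matches) and `nTemplates`.
#' @export
matchCounts <- function(x) {
  stopifnot(is(x, "SampEnResult"))
  c(A = x@A, B = x@B, nTemplates = as.numeric(x@nTemplates))
}

#' Per-cycle amplitudes
#'
#' @param x a [CycleAmplitudes-class].
#' @return numeric vector of per-cycle amplitudes, degrees.
#' @export
cycleAmplitudes <- function(x) {
  stopifnot(is(x, "CycleAmplitudes"))
  x@amplitudes
}

#' Mean cycle amplitude
#'
#' @param x a [CycleAmplitudes-class].
#' @return mean amplitude in degrees.
#' @export
meanAmplitude <- function(x) {
  stopifnot(is(x, "CycleAmplitudes"))
  x@meanAmplitude
}

#' Number of detected cycles
#'
#' @param x a [CycleAmplitudes-class].
#' @return integer cycle count.
#' @export
nCycles <- function(x) {
  stopifnot(is(x, "CycleAmplitudes"))
  x@nCycles
}

setMethod("show", "IMURecording", function(object) {
  m <- object@meta
  cat(sprintf("IMURecording: %d samples x 6 channels @ %g Hz (%.2f s)\n",
              nSamples(object), samplingRate(object), duration(object)))
  if (!is.null(m$participant) || !is.null(m$condition)) {
    cat(sprintf("  participant: %s  condition: %s\n",
                m$participant %||% "<none>", m$condition %||% "<none>"))
  }
})

setMethod("show", "TrimmedSeries", function(object) {
  cat(sprintf("TrimmedSeries %s: %d samples @ %g Hz, span [%d, %d)\n",
              object@channel, nSamples(object), samplingRate(object),
              object@startIndex, object@endIndex))
})

setMethod("show", "AngleTrace", function(object) {
  cat(sprintf("AngleTrace: %d samples @ %g Hz, range [%.2f, %.2f] deg%s\n",
              length(object@angle), object@samplingRate,
              min(object@angle), max(object@angle),
              if (object@detrended) ", detrended" else ""))
})

setMethod("show", "CycleAmplitudes", function(object) {
  cat(sprintf("CycleAmplitudes: %d cycles, mean amplitude %.2f deg (range %.2f-%.2f)\n",
              object@nCycles, object@meanAmplitude,
              min(object@amplitudes), max(object@amplitudes)))
})

setMethod("show", "SampEnResult", function(object) {
  if (object@undefined) {
    cat(sprintf("SampEn undefined (A=%g, B=%g; too few matches), m=%d, r=%g (%s)\n",
                object@A, object@B, object@m, object@rValue, object@rMode))
  } else {
    cat(sprintf("SampEn = %.4f nats (A=%g, B=%g, N=%d), m=%d, r=%g (%s, abs %.4g)\n",
                object@sampen, object@A, object@B, object@n, object@m,
                object@rValue, object@rMode, object@rAbs))
  }
})
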