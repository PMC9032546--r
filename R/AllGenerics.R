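#' Sampling rate accessor
#'
#' @param object an [IMURecording-class], [TrimmedSeries-class] or
#'   [AngleTrace-class].
#' @return sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Number of samples
#'
#' @param object an [IMURecording-class] or [TrimmedSeries-class].
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' Recording duration in seconds
#'
#' Defined as `nSamples / samplingRate`, so a 12,000-sample recording at
#' 100 Hz reports 120.00 s.
#'
#' @param object an [IMURecording-class] or [TrimmedSeries-class].
#' @return duration in seconds.
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
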