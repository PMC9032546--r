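#' Integrate GyrX into a trunk pitch angle trace
#'
#' Cumulative trapezoidal integration of the sagittal-plane angular velocity,
#' `dt = 1/samplingRate`, with the integration constant fixed so the trace
#' starts at 0 degrees.  Raw gyroscope integration drifts under a constant
#' bias, so by default a linear trend fitted to the integrated trace is
#' subtracted (slope only, so the trace stays anchored at zero); the flag is
#' recorded on the returned object.
#'
#' @param gyrX a [TrimmedSeries-class] of the GyrX channel, or a numeric
#'   vector of angular velocities in degrees/s (then `samplingRate` must be
#'   given).
#' @param detrend remove a fitted linear drift (default `TRUE`).
#' @param samplingRate sampling frequency in Hz; taken from `gyrX` when it is
#'   a [TrimmedSeries-class].
#' @return an [AngleTrace-class] in degrees.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' w <- 90 * cos(2 * pi * 0.5 * t)   # deg/s
#' a <- integrateGyro(w, detrend = FALSE, samplingRate = 100)
#' max(angleValues(a))               # ~ 90 / pi = 28.65 deg
#' @export
integrateGyro <- function(gyrX, detrend = TRUE, samplingRate = NULL) {
  if (is(gyrX, "TrimmedSeries")) {
    fs <- samplingRate(gyrX)
    v <- trimmedValues(gyrX)
  } else {
    if (is.null(samplingRate)) {
      stop("samplingRate is required when gyrX is a plain numeric vector")
    }
    fs <- samplingRate
    v <- as.numeric(gyrX)
  }
  if (length(v) < 2L) stop("series too short to integrate")
  angle <- as.numeric(pracma::cumtrapz(v)) / fs
  angle <- angle - angle[1]
  if (detrend) {
    tIdx <- seq_along(angle)
    fit <- stats::lm.fit(cbind(1, tIdx), angle)
    slope <- fit$coefficients[2]
    angle <- angle - slope * (tIdx - 1)   # remove drift, keep angle[1] = 0
  }
  new("AngleTrace", angle = angle, samplingRate = fs,
      detrended = detrend, method = "trapezoid")
}

# prominence of each extremum index in `a` (maxima when type = 1, computed on
# -a for minima): height above the higher of the two bases reached before a
# larger extremum bounds the peak on each side
peakProminence <- function(a, idx) {
  vapply(idx, function(i) {
    v <- a[i]
    li <- i
    baseL <- v
    while (li > 1L) {
      li <- li - 1L
      if (a[li] > v) break
      if (a[li] < baseL) baseL <- a[li]
    }
    ri <- i
    baseR <- v
    n <- length(a)
    while (ri < n) {
      ri <- ri + 1L
      if (a[ri] > v) break
      if (a[ri] < baseR) baseR <- a[ri]
    }
    v - max(baseL, baseR)
  }, numeric(1))
}

# local extrema by sign change of the first difference (plateaus carried
# forward); returns 1-based indices
localExtrema <- function(a) {
  d <- diff(a)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(0), minima = integer(0)))
  sFilled <- s
  last <- 0
  for (i in seq_along(sFilled)) {
    if (sFilled[i] == 0) sFilled[i] <- last else last <- sFilled[i]
  }
  turns <- diff(sFilled)
  maxima <- which(turns < 0) + 1L
  minima <- which(turns > 0) + 1L
  list(maxima = maxima, minima = minima)
}

#' Detect bending cycles and their amplitudes in an angle trace
#'
#' Identifies the successive minimum and maximum angles of the repeated
#' bending cycles and computes the consecutive amplitudes
#' `A_i = max_i - min_i` and their mean.  Extrema must have prominence of at
#' least `minProminenceFrac` times the global range of the trace and be
#' separated by at least `minSeparation` seconds from the previous extremum
#' of the same type (the more extreme one is kept otherwise).  Alternation
#' is then enforced by keeping the most extreme value within runs of
#' same-type extrema, and each minimum is paired with the following maximum.
#' The first and last samples are admitted as boundary extrema so that a
#' trace that starts and ends at the neutral position yields one amplitude
#' per cycle.
#'
#' @param angle an [AngleTrace-class] (or numeric vector of angles in
#'   degrees with `samplingRate` supplied).
#' @param minProminenceFrac minimum prominence as a fraction of the global
#'   range (default 0.2).
#' @param minSeparation minimum separation between same-type extrema,
#'   seconds; default half the median cycle period estimated from
#'   zero crossings of the centred trace.
#' @param samplingRate Hz, needed only for plain numeric input.
#' @return a [CycleAmplitudes-class].
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' a <- integrateGyro(60 * pi * sin(2 * pi * t / 2) / 2,
#'                    detrend = FALSE, samplingRate = 100)
#' detectCycles(a)
#' @export
detectCycles <- function(angle, minProminenceFrac = 0.2,
                         minSeparation = NULL, samplingRate = NULL) {
  if (is(angle, "AngleTrace")) {
    a <- angleValues(angle)
    fs <- samplingRate(angle)
  } else {
    if (is.null(samplingRate)) {
      stop("samplingRate is required when angle is a plain numeric vector")
    }
    a <- as.numeric(angle)
    fs <- samplingRate
  }
  rng <- max(a) - min(a)
  if (rng == 0) stop("insufficient cycles: flat angle trace")

  if (is.null(minSeparation)) {
    centred <- a - mean(a)
    up <- which(centred[-length(centred)] < 0 & centred[-1] >= 0)
    minSeparation <- if (length(up) >= 2L) {
      0.5 * stats::median(diff(up)) / fs
    } else 0
  }
  minSepSamples <- minSeparation * fs

  ext <- localExtrema(a)
  maxima <- ext$maxima
  minima <- ext$minima

  promMax <- peakProminence(a, maxima)
  promMin <- peakProminence(-a, minima)
  maxima <- maxima[promMax >= minProminenceFrac * rng]
  minima <- minima[promMin >= minProminenceFrac * rng]
  if (!length(maxima) || !length(minima)) {
    stop("insufficient cycles: no prominent extrema found")
  }

  # boundary samples as candidate extrema of the complementary type, so a
  # trace starting/ending at the neutral position contributes its first and
  # last half-cycles (added after the prominence filter: low-prominence
  # noise wiggles must not decide the boundary type)
  firstInterior <- min(c(maxima, minima))
  if (firstInterior %in% maxima) minima <- c(1L, minima)
  else maxima <- c(1L, maxima)
  lastInterior <- max(c(maxima, minima))
  n <- length(a)
  if (lastInterior < n) {
    if (lastInterior %in% maxima) minima <- c(minima, n)
    else maxima <- c(maxima, n)
  }

  # same-type separation: within a run closer than minSepSamples keep the
  # more extreme value
  enforceSep <- function(idx, val) {
    if (length(idx) < 2L) return(idx)
    keep <- idx[1]
    out <- integer(0)
    for (i in idx[-1]) {
      if (i - keep < minSepSamples) {
        if (val[i] > val[keep]) keep <- i
      } else {
        out <- c(out, keep)
        keep <- i
      }
    }
    c(out, keep)
  }
  maxima <- enforceSep(maxima, a)
  minima <- enforceSep(minima, -a)

  # alternation: merge runs of same-type extrema keeping the extreme value,
  # ties broken by earliest index
  allIdx <- c(maxima, minima)
  allType <- c(rep(1L, length(maxima)), rep(-1L, length(minima)))
  o <- order(allIdx)
  allIdx <- allIdx[o]
  allType <- allType[o]
  keptIdx <- integer(0)
  keptType <- integer(0)
  for (i in seq_along(allIdx)) {
    if (length(keptType) && keptType[length(keptType)] == allType[i]) {
      j <- length(keptIdx)
      better <- if (allType[i] == 1L) a[allIdx[i]] > a[keptIdx[j]]
                else a[allIdx[i]] < a[keptIdx[j]]
      if (better) keptIdx[j] <- allIdx[i]
    } else {
      keptIdx <- c(keptIdx, allIdx[i])
      keptType <- c(keptType, allType[i])
    }
  }

  minIdx <- keptIdx[keptType == -1L]
  maxIdx <- keptIdx[keptType == 1L]
  # forward pairing: each minimum with the following maximum
  amps <- numeric(0)
  pairMin <- integer(0)
  pairMax <- integer(0)
  for (mi in minIdx) {
    nxt <- maxIdx[maxIdx > mi]
    if (length(nxt)) {
      amps <- c(amps, a[nxt[1]] - a[mi])
      pairMin <- c(pairMin, mi)
      pairMax <- c(pairMax, nxt[1])
    }
  }
  if (length(amps) < 2L) stop("insufficient cycles")

  new("CycleAmplitudes",
      minima = data.frame(index = minIdx, angle = a[minIdx]),
      maxima = data.frame(index = maxIdx, angle = a[maxIdx]),
      amplitudes = amps,
      meanAmplitude = mean(amps),
      nCycles = length(amps))
}

#' Standard deviations of the angular velocities
#'
#' Population SD (divisor N) of the three gyroscope channels over the
#' trimmed test span: SDX, SDY and SDZ, the magnitude-of-variability
#' descriptors of the test.
#'
#' @param trimmed output of [segmentTest()] (named list containing `GyrX`,
#'   `GyrY`, `GyrZ` [TrimmedSeries-class] objects).
#' @return named numeric vector `c(sdX =, sdY =, sdZ =)` in degrees/s.
#' @export
velocitySds <- function(trimmed) {
  need <- c("GyrX", "GyrY", "GyrZ")
  if (!all(need %in% names(trimmed))) {
    stop("trimmed must contain GyrX, GyrY and GyrZ")
  }
  c(sdX = popSd(trimmedValues(trimmed$GyrX)),
    sdY = popSd(trimmedValues(trimmed$GyrY)),
    sdZ = popSd(trimmedValues(trimmed$GyrZ)))
}
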