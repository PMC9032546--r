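#' Parameters of a simulated participant
#'
#' Describes one participant performing repeated trunk bending-and-return
#' cycles.  Cycle durations and peak angles vary from cycle to cycle
#' (truncated-normal draws), and all channels carry stationary AR(1) sensor
#' noise whose SD acts as a complexity knob: more noise makes the series less
#' predictable and raises its Sample Entropy.
#'
#' @param meanCycleDuration mean duration of one bending cycle, seconds (> 0).
#' @param cvCycleDuration coefficient of variation of cycle duration (>= 0).
#'   Durations are truncated to `[0.3, 3] * meanCycleDuration`.
#' @param meanAmplitude mean peak trunk-pitch angle per cycle, degrees (> 0).
#' @param cvAmplitude coefficient of variation of peak angle (>= 0);
#'   draws truncated to positive values.
#' @param noiseSdGyro stationary SD of AR(1) noise on gyroscope channels,
#'   degrees/s (>= 0).
#' @param noiseSdAcc stationary SD of AR(1) noise on accelerometer channels,
#'   g (>= 0).
#' @param noiseAr1 AR(1) coefficient of the sensor noise, in `[0, 1)`.
#' @param nCycles number of bending cycles (default 50, the clinical test).
#' @param samplingRate sampling frequency, Hz (default 100).
#' @param sensorRadius effective lever arm for the centripetal acceleration
#'   that sagittal rotation induces on AccZ, metres (default 0.2).
#' @param gyrZCoupling fraction of GyrX leaking into GyrZ (default 0.1),
#'   mimicking slight sensor misalignment.
#' @param seed integer RNG seed, or `NULL` to use the current RNG stream.
#' @return a validated list of class `ParticipantParams`.
#' @examples
#' p <- participantParams(meanAmplitude = 60, meanCycleDuration = 2)
#' rec <- simulateRecording(p, seed = 1)
#' @export
participantParams <- function(meanCycleDuration = 2.05,
                              cvCycleDuration = 0.05,
                              meanAmplitude = 22,
                              cvAmplitude = 0.05,
                              noiseSdGyro = 2,
                              noiseSdAcc = 0.02,
                              noiseAr1 = 0.9,
                              nCycles = 50L,
                              samplingRate = 100,
                              sensorRadius = 0.2,
                              gyrZCoupling = 0.1,
                              seed = NULL) {
  checkPositiveScalar(meanCycleDuration, "meanCycleDuration")
  checkNonNegativeScalar(cvCycleDuration, "cvCycleDuration")
  checkPositiveScalar(meanAmplitude, "meanAmplitude")
  checkNonNegativeScalar(cvAmplitude, "cvAmplitude")
  checkNonNegativeScalar(noiseSdGyro, "noiseSdGyro")
  checkNonNegativeScalar(noiseSdAcc, "noiseSdAcc")
  if (length(noiseAr1) != 1L || !is.finite(noiseAr1) ||
      noiseAr1 < 0 || noiseAr1 >= 1) {
    stop("parameter 'noiseAr1' must lie in [0, 1)")
  }
  checkPositiveScalar(nCycles, "nCycles")
  checkPositiveScalar(samplingRate, "samplingRate")
  checkNonNegativeScalar(sensorRadius, "sensorRadius")
  structure(list(
    meanCycleDuration = meanCycleDuration,
    cvCycleDuration = cvCycleDuration,
    meanAmplitude = meanAmplitude,
    cvAmplitude = cvAmplitude,
    noiseSdGyro = noiseSdGyro,
    noiseSdAcc = noiseSdAcc,
    noiseAr1 = noiseAr1,
    nCycles = as.integer(nCycles),
    samplingRate = samplingRate,
    sensorRadius = sensorRadius,
    gyrZCoupling = gyrZCoupling,
    seed = seed
  ), class = "ParticipantParams")
}

#' Layout of a simulated recording
#'
#' The recording mirrors the clinical protocol: quiet standing, a left-right
#' rotation marker used later to localise the start of the cycles, a short
#' pause, the bending cycles, and a quiet tail.  The marker is expressed on
#' GyrY (rotation about the vertical axis as worn) as two opposite
#' raised-cosine lobes.
#'
#' @param leadIn quiet standing before the marker, seconds (>= 0, default 2).
#' @param marker marker duration, seconds (default 1.5).
#' @param markerAmplitude peak angular velocity of the marker lobes,
#'   degrees/s (default 60); must exceed 5x the gyro noise SD so the marker
#'   is detectable.
#' @param pause quiet interval between marker and first cycle, seconds
#'   (default 1).
#' @param tail quiet standing after the last cycle, seconds (default 2).
#' @return a validated list of class `RecordingLayout`.
#' @export
recordingLayout <- function(leadIn = 2, marker = 1.5, markerAmplitude = 60,
                            pause = 1, tail = 2) {
  checkNonNegativeScalar(leadIn, "leadIn")
  checkPositiveScalar(marker, "marker")
  checkPositiveScalar(markerAmplitude, "markerAmplitude")
  checkNonNegativeScalar(pause, "pause")
  checkNonNegativeScalar(tail, "tail")
  structure(list(leadIn = leadIn, marker = marker,
                 markerAmplitude = markerAmplitude,
                 pause = pause, tail = tail),
            class = "RecordingLayout")
}

#' Simulate one IMU recording of the bending-and-return test
#'
#' Generates six synchronized channels at `samplingRate` Hz.  Within cycle c
#' of duration `T_c` and peak angle `A_c`, the trunk pitch follows the
#' raised-cosine profile `theta(tau) = A_c (1 - cos 2 pi tau) / 2` for cycle
#' phase `tau` in `[0, 1)`, which is smooth with zero angular velocity at the
#' end points.  The channels are then
#' \itemize{
#'   \item GyrX: the analytic pitch velocity `A_c pi sin(2 pi tau) / T_c`
#'     (degrees/s) plus AR(1) noise;
#'   \item GyrY: the marker pulse plus AR(1) noise;
#'   \item GyrZ: AR(1) noise plus `gyrZCoupling * GyrX`;
#'   \item AccY: `cos(theta)` g (gravity projection) plus noise;
#'   \item AccZ: `sin(theta)` g plus the centripetal term
#'     `(GyrX in rad/s)^2 * sensorRadius / 9.81` plus noise;
#'   \item AccX: AR(1) noise only (no planned movement along X).
#' }
#' Noise is stationary AR(1) with coefficient `noiseAr1` and stationary SD
#' `noiseSdGyro` (gyro channels) or `noiseSdAcc` (accelerometer channels).
#'
#' Ground truth (cycle onset/offset sample indices, per-cycle durations and
#' amplitudes) is stored in the recording metadata under `groundTruth`.
#'
#' @param params a [participantParams()] object.
#' @param layout a [recordingLayout()] object.
#' @param participant,condition metadata labels.
#' @param seed overrides `params$seed` when non-`NULL`.
#' @return an [IMURecording-class].
#' @examples
#' rec <- simulateRecording(participantParams(nCycles = 10), seed = 7)
#' rec
#' @export
simulateRecording <- function(params = participantParams(),
                              layout = recordingLayout(),
                              participant = "sim", condition = "stool",
                              seed = NULL) {
  stopifnot(inherits(params, "ParticipantParams"),
            inherits(layout, "RecordingLayout"))
  if (params$noiseSdGyro > 0 &&
      layout$markerAmplitude <= 5 * params$noiseSdGyro) {
    stop("marker amplitude must exceed 5x the gyro noise SD for the marker ",
         "to be detectable")
  }
  seed <- seed %||% params$seed
  withSeed(seed, {
    fs <- params$samplingRate
    dt <- 1 / fs

    # per-cycle draws
    nc <- params$nCycles
    Tc <- vapply(seq_len(nc), function(i) {
      rnormTrunc(params$meanCycleDuration,
                 params$cvCycleDuration * params$meanCycleDuration,
                 lower = 0.3 * params$meanCycleDuration,
                 upper = 3 * params$meanCycleDuration)
    }, numeric(1))
    Ac <- vapply(seq_len(nc), function(i) {
      rnormTrunc(params$meanAmplitude,
                 params$cvAmplitude * params$meanAmplitude,
                 lower = .Machine$double.eps)
    }, numeric(1))
    nPerCycle <- pmax(2L, as.integer(round(Tc * fs)))
    TcEff <- nPerCycle / fs

    # signal segments: theta (deg) and its analytic derivative (deg/s)
    theta <- numeric(0)
    gyrx <- numeric(0)
    for (c in seq_len(nc)) {
      tau <- (seq_len(nPerCycle[c]) - 1L) / nPerCycle[c]
      theta <- c(theta, Ac[c] * (1 - cos(2 * pi * tau)) / 2)
      gyrx <- c(gyrx, Ac[c] * pi * sin(2 * pi * tau) / TcEff[c])
    }

    nLead <- as.integer(round(layout$leadIn * fs))
    nMarker <- as.integer(round(layout$marker * fs))
    nPause <- as.integer(round(layout$pause * fs))
    nTail <- as.integer(round(layout$tail * fs))
    nCyc <- length(theta)
    n <- nLead + nMarker + nPause + nCyc + nTail

    # marker: two opposite raised-cosine lobes on GyrY
    tauM <- (seq_len(nMarker) - 1L) / nMarker
    lobe <- ifelse(tauM < 0.5,
                   (1 - cos(4 * pi * tauM)) / 2,
                   -(1 - cos(4 * pi * (tauM - 0.5))) / 2)
    markerSig <- layout$markerAmplitude * lobe

    cycStart <- nLead + nMarker + nPause          # 0-based index of 1st sample
    thetaFull <- numeric(n)
    gyrxFull <- numeric(n)
    thetaFull[cycStart + seq_len(nCyc)] <- theta
    gyrxFull[cycStart + seq_len(nCyc)] <- gyrx
    gyrYSig <- numeric(n)
    gyrYSig[nLead + seq_len(nMarker)] <- markerSig

    thetaRad <- thetaFull * pi / 180
    gyrxRad <- gyrxFull * pi / 180
    centripetal <- gyrxRad^2 * params$sensorRadius / 9.81   # in g

    sg <- params$noiseSdGyro
    sa <- params$noiseSdAcc
    phi <- params$noiseAr1
    data <- cbind(
      AccX = ar1Noise(n, sa, phi),
      AccY = cos(thetaRad) + ar1Noise(n, sa, phi),
      AccZ = sin(thetaRad) + centripetal + ar1Noise(n, sa, phi),
      GyrX = gyrxFull + ar1Noise(n, sg, phi),
      GyrY = gyrYSig + ar1Noise(n, sg, phi),
      GyrZ = params$gyrZCoupling * gyrxFull + ar1Noise(n, sg, phi)
    )

    new("IMURecording",
        data = data,
        time = (seq_len(n) - 1L) / fs,
        samplingRate = fs,
        meta = list(
          participant = participant,
          condition = condition,
          notes = "synthetic bending-and-return recording",
          groundTruth = list(
            cycleStart = cycStart,               # 0-based, first cycle sample
            cycleEnd = cycStart + nCyc,          # half-open
            nCycles = nc,
            cycleDurations = TcEff,
            cycleAmplitudes = Ac,
            params = unclass(params)[setdiff(names(params), "seed")],
            layout = unclass(layout),
            seed = seed
          )
        ))
  })
}

#' Simulate a cohort of paired-condition recordings
#'
#' Each participant performs the test under two conditions that differ the
#' way a deep (floor box) and a shallow (stool) target differ: the box-like
#' condition has a larger bending amplitude and a slightly longer cycle, so
#' its angular-velocity SD (SDX) is larger.  Both recordings of a participant
#' share the same between-subject draw; only the condition offsets differ.
#'
#' @param nParticipants number of participants (>= 2, default 23).
#' @param base [participantParams()] describing the stool-like condition.
#' @param betweenSubjectCV coefficient of variation of the per-participant
#'   multiplicative factors applied to mean amplitude and mean cycle
#'   duration (independent draws; default 0.2).  The amplitude factor is
#'   truncated to `[0.3, 3]`; the duration factor to `[0.72, 1.45]`, so that
#'   a 50-cycle stool-like test always spans at least ~74 s — the observed
#'   range of such tests (roughly 72 to 148 s) — and the full 70 s
#'   convergence window is available for every participant.
#' @param boxAmplitudeFactor,boxDurationFactor multiplicative condition
#'   offsets turning the stool-like base into the box-like condition
#'   (defaults 1.6 and 1.09).
#' @param layout [recordingLayout()] shared by all recordings.
#' @param seed integer seed; the cohort is fully deterministic given it.
#' @return list of length `nParticipants`; each element is
#'   `list(participant =, box =, stool =)` with two [IMURecording-class]
#'   objects.
#' @examples
#' coh <- simulateCohort(nParticipants = 2,
#'                       base = participantParams(nCycles = 10), seed = 1)
#' coh[[1]]$box
#' @export
simulateCohort <- function(nParticipants = 23L,
                           base = participantParams(),
                           betweenSubjectCV = 0.2,
                           boxAmplitudeFactor = 1.6,
                           boxDurationFactor = 1.09,
                           layout = recordingLayout(),
                           seed = NULL) {
  if (nParticipants < 2L) stop("nParticipants must be at least 2")
  stopifnot(inherits(base, "ParticipantParams"))
  checkNonNegativeScalar(betweenSubjectCV, "betweenSubjectCV")
  withSeed(seed, {
    lapply(seq_len(nParticipants), function(i) {
      fA <- rnormTrunc(1, betweenSubjectCV, lower = 0.3, upper = 3)
      fT <- rnormTrunc(1, betweenSubjectCV, lower = 0.72, upper = 1.45)
      mk <- function(ampFactor, durFactor) {
        p <- base
        p$meanAmplitude <- base$meanAmplitude * fA * ampFactor
        p$meanCycleDuration <- base$meanCycleDuration * fT * durFactor
        p
      }
      id <- sprintf("P%02d", i)
      recSeeds <- sample.int(.Machine$integer.max - 1L, 2L)
      list(
        participant = id,
        box = simulateRecording(mk(boxAmplitudeFactor, boxDurationFactor),
                                layout, participant = id, condition = "box",
                                seed = recSeeds[1]),
        stool = simulateRecording(mk(1, 1), layout,
                                  participant = id, condition = "stool",
                                  seed = recSeeds[2])
      )
    })
  })
}
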