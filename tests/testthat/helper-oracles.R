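# Independent oracles and fixture builders shared by the tests.

# seeded AR(1) series used as a generic "physiological-like" fixture
ar1Series <- function(n, phi = 0.5, sd = 1, seed = 1) {
  set.seed(seed)
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# exact two-sided Wilcoxon signed-rank p-value by enumeration over all
# 2^k sign assignments of the non-zero differences (requires distinct |d|)
signedRankEnumerationP <- function(d) {
  d <- d[d != 0]
  k <- length(d)
  stopifnot(k >= 1, k <= 15, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  vAll <- as.numeric(signs %*% rk)
  pLe <- mean(vAll <= v)
  pGe <- mean(vAll >= v)
  min(1, 2 * min(pLe, pGe))
}

# reconstruct the noiseless pitch-angle profile from a recording's stored
# ground truth (independent of the integration code under test)
groundTruthTheta <- function(rec) {
  gt <- imuMeta(rec)$groundTruth
  fs <- samplingRate(rec)
  theta <- numeric(0)
  for (c in seq_len(gt$nCycles)) {
    nPer <- round(gt$cycleDurations[c] * fs)
    tau <- (seq_len(nPer) - 1L) / nPer
    theta <- c(theta, gt$cycleAmplitudes[c] * (1 - cos(2 * pi * tau)) / 2)
  }
  theta
}

# a small noiseless recording used across kinematics tests
noiselessRecording <- function(meanAmplitude = 60, meanCycleDuration = 2,
                               nCycles = 50L) {
  simulateRecording(
    participantParams(meanAmplitude = meanAmplitude,
                      meanCycleDuration = meanCycleDuration,
                      cvCycleDuration = 0, cvAmplitude = 0,
                      noiseSdGyro = 0, noiseSdAcc = 0, nCycles = nCycles),
    seed = 1)
}
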