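---
title: "Methods: entropy-based analysis of repeated trunk bending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-based analysis of repeated trunk bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkentropy)
```

## The measurement and its analysis

A participant stands upright, bends the trunk to touch a target and
returns, repeatedly (typically 50 cycles), with a small IMU fixed over the
sacrum.  As worn, the X axis points left, Y up and Z backward, so the
sagittal bending appears mainly as rotation about X (channel GyrX) while
gravity projects onto AccY and AccZ as the trunk pitches.  Recordings are
sampled at 100 Hz and last roughly two minutes (about 12,000 samples).  Two
target heights are used in randomized order: a low, box-like target on the
floor, which forces a deeper and faster movement, and a higher, stool-like
target.

The analysis chain is:

1. **Trimming** (`segmentTest()`): the protocol asks for a left–right
   rotation just before the first cycle; its pulse on GyrY localises the
   test start.  The trim runs from the sample nearest zero on GyrX after
   the marker and before the first cycle launches, to the last near-zero
   sample after the final cycle.
2. **Kinematics** (`integrateGyro()`, `detectCycles()`, `velocitySds()`):
   cumulative trapezoidal integration of GyrX gives the pitch-angle trace;
   alternating minima/maxima give per-cycle amplitudes
   $A_i = \max_i - \min_i$; population SDs of the three gyro channels give
   SDX/SDY/SDZ, the magnitude-of-variability descriptors.
3. **Complexity** (`sampEn()`): Sample Entropy of each channel over the
   trimmed span ("SampEn50" for a 50-cycle test).
4. **Duration shortening** (`sampEnPartials()`, `regressThroughOrigin()`,
   `selectDuration()`, `blandAltman()`): SampEn on windows
   $[10\,\mathrm{s}, I\,\mathrm{s})$, $I = 12, 14, \dots, 70$, regressed
   through the origin on SampEn50 across participants; the optimal test
   duration is the smallest $I$ with $R^2 > 0.99$ and slope $k > 0.95$.
   Bland–Altman bias and limits of agreement quantify the residual
   disagreement at a chosen $I$.

## Sample Entropy: definition and conventions

With templates $u_i = (x_i,\dots,x_{i+m-1})$, $i = 1 \dots N-m$,

$$\mathrm{SampEn}(m, r, N) = -\ln\frac{A}{B},$$

where $B$ counts ordered pairs $(i,j)$, $i \ne j$, matching within
Chebyshev distance $r$ (inclusive) at length $m$, and $A$ the same pairs at
length $m+1$.  Conventions adopted, all exposed as parameters because
published analyses vary in them:

* **Counting range.** Both counts run over $i, j \le N-m$, so $A \le B$
  always holds and $A/B$ is a conditional probability.  One consequence
  worth knowing: time reversal maps this template window onto
  $[2, N-m+1]$, so $A$ is exactly reversal-invariant while $B$ can change
  by a handful of boundary pairs — the entropy changes by a correspondingly
  negligible amount, and the tests check exactly that.
* **Tolerance.** Default $r = 0.2 \times$ SD with the *population* SD
  (divisor $N$); this makes the relative-mode result invariant under affine
  rescaling of the series.  Absolute tolerances are available.
* **Embedding.** Default $m = 2$, the standard choice for short
  physiological series.
* **Short series.** A hard floor of 200 samples (configurable) is enforced;
  SampEn is considered unreliable below it.  When no pairs match
  ($A = 0$ or $B = 0$) the result carries an `undefined` flag rather than
  an infinite value, so cohort aggregation can skip it.
* **Exactness.** The production counter is an exhaustive compiled double
  loop; `sampEnOracle()` is an independent plain-R transcription of the
  definition, and the test suite requires bit-exact agreement of $A$ and
  $B$ between the two on hundreds of random series (lengths 200–1,000).

## Windowed convergence

Windows are exact sample ranges relative to the trim start: window $I$
covers samples $[10 f_s, I f_s)$, i.e. $(I-10) \cdot 100$ samples at
100 Hz, so the 2 s increment adds exactly 200 samples.  The first 10 s are
excluded as habituation.  In relative mode the tolerance is resolved
*per window* (each window's own SD); this keeps each window self-contained
and is the convention of the short-series entropy literature.  A
`rScope = "full"` switch resolves it once from the full series instead, for
sensitivity checks.  The final window of a 70 s span is, by construction,
identical to SampEn of samples $[1000, 7000)$ — the tests assert this
identity exactly.

## Agreement layer

* **Through-origin regression** $y = kx$: $k = \sum xy / \sum x^2$, and
  $R^2 = 1 - \sum(y-kx)^2 / \sum y^2$ with the *uncentered* total sum of
  squares — the standard convention for no-intercept fits (the centered
  variant can leave $[0,1]$ and is available as an option).
* **Bland–Altman**: bias = mean difference, limits = bias $\pm\,1.96$
  sample SD of the differences.  The 1.96 multiplier is consistent with
  published bias/limit pairs this package was checked against
  (e.g. a bias of −0.0052 with SD 0.0105 gives limits −0.0258 and 0.0154).
* **Condition contrasts**: Wilcoxon signed-rank (exact null for $n \le 25$
  without ties, normal approximation with corrections otherwise) for
  durations, SDs and SampEn; paired t for amplitudes; two-sided, 5%
  significance level, no multiple-testing correction — matching common
  practice for this design.

## The synthetic generator

`simulateRecording()` builds a recording as: quiet lead-in (2 s) → marker
(1.5 s, two opposite ±60 °/s raised-cosine lobes on GyrY, a convention for
the left–right rotation since its exact channel signature is not
standardised) → pause (1 s) → $n$ bending cycles → quiet tail (2 s).
Within a cycle of duration $T_c$ and peak angle $A_c$ the pitch follows the
raised cosine $\theta(\tau) = A_c (1 - \cos 2\pi\tau)/2$ — the simplest
$C^1$ profile with zero end-point velocity.  $T_c$ and $A_c$ are
truncated-normal draws (truncation $[0.3, 3] \times$ mean for $T_c$,
positive for $A_c$), modelling cycle-to-cycle motor variability.  Channels
follow the rigid-sensor physics: GyrX is the analytic $\dot\theta$; AccY
and AccZ carry the gravity projections $\cos\theta$ and $\sin\theta$; AccZ
additionally carries the centripetal term
$\omega^2 \cdot \text{sensorRadius} / 9.81$ (default lever arm 0.2 m),
because rotation about X accelerates the sensor along Z; GyrZ receives a
small (10%) coupling of GyrX mimicking mounting misalignment; AccX is noise
only, as no planned movement occurs along X.  All channels carry stationary
AR(1) noise (default coefficient 0.9 — sensor noise and physiological
tremor are strongly autocorrelated at 100 Hz, and SampEn is sensitive to
that structure, which white noise would misrepresent).  The gyro noise SD
(default 2 °/s) is the *complexity knob*: the tests verify that mean GyrX
SampEn increases monotonically in it.

`simulateCohort()` draws per-participant multiplicative factors for mean
amplitude and mean cycle duration (CV 0.2, shared between a participant's
two conditions) around a stool-like base of 22° and 2.05 s, with the
box-like condition scaled by 1.6 in amplitude and 1.09 in duration.  These
values were chosen once from the published cohort geometry for this task —
they give SDX of roughly 34 °/s (box) versus 24 °/s (stool) and mean
durations near 112 versus 103 s, with between-subject spreads comparable to
the printed ones.  The duration factor is truncated to $[0.72, 1.45]$ so a
50-cycle stool test always spans at least ~74 s, mirroring the observed
duration range (all recorded tests exceeded 72 s) and guaranteeing the full
70 s convergence window.

What the generator does **not** emulate: multi-joint coordination (hip,
knee, ankle contributions and their redistribution with fatigue), drift in
movement tempo, non-stationary habituation dynamics beyond the excluded
first 10 s, magnetometer output, and any pathology-specific dynamics.
Passing tests therefore demonstrate correctness of the computational chain
and the stated statistical behaviour on quasi-periodic signals with
realistic noise — not clinical validity on patient data.

## Numerical and robustness choices

* **Segmentation thresholds.**  Marker detection requires the smoothed
  rectified marker channel to exceed 5 × `zeroTol` (default
  `zeroTol` = 2 °/s); the marker end is the last crossing of half the
  marker peak; the cycle launch threshold is 10% of the post-marker GyrX
  envelope peak.  Threshold crossings are evaluated on a 0.15 s
  moving-average envelope and must persist for 0.2 s, because AR(1) noise
  produces brief spurious excursions that a sustained-run rule rejects;
  the nearest-zero endpoint search then runs on the raw samples.
* **Integration drift.**  Linear detrending of the integrated angle is on
  by default: a constant gyro bias $b$ integrates to a ramp, and removing a
  fitted slope (keeping the trace anchored at 0°) changes the mean
  amplitude by under 2% for $|b| \le 1$ °/s over a 100 s trace, as the
  tests verify.  Whether to detrend before peak detection is genuinely
  open; the flag is exposed and recorded in the output.
* **Cycle detection.**  Extrema need prominence ≥ 0.2 × the global range
  and separation ≥ half the median zero-crossing period; runs of same-type
  extrema are merged keeping the more extreme value (ties: earliest index);
  each minimum is paired with the following maximum.  The first/last
  samples are admitted as boundary extrema so a trace that starts and ends
  at the neutral position yields exactly one amplitude per cycle.
* **Index conventions.**  0-based, half-open `[start, end)` spans
  throughout the trimming layer; 1-based sample indices inside R vectors.
* **Report determinism.**  `runPipeline()` reports carry no timestamps and
  serialize deterministically, so a rerun with the same seed and config is
  byte-identical.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data built at test time: oracle
equivalence on 100 series of 200–1,000 samples; segmentation and cycle
recovery on 50-cycle recordings across seeds; qualitative cohort orderings
(AccX vs GyrX entropy, box vs stool SDX, correlation growth with window
length) on twenty 23-participant cohorts; pipeline integration on
4-participant, 15-cycle cohorts.  These sizes were chosen to exercise every
code path at full cohort scale where the property needs it and at reduced
scale where it does not.

## Known limitations

* Segmentation automates what is, in practice, often a manual visual step;
  on atypical recordings (missing marker, aborted cycles) it fails loudly
  rather than guessing, and the pipeline skips such recordings with a
  logged reason.
* Only the sagittal amplitude is computed; frontal/transverse amplitudes
  and sensor-fusion orientation estimation are out of scope.
* SampEn parameter conventions differ across published analyses; when
  comparing against external values, check $m$, $r$, the SD convention and
  the counting range first — all are explicit parameters here.
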