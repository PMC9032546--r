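# trunkentropy

Movement-complexity analysis of repeated trunk bending-and-return tests
recorded by a single sacrum-mounted inertial measurement unit (IMU).

Low back pain is associated with more stereotyped, less complex lumbopelvic
movement.  A practical way to quantify that complexity in the clinic is to
have the patient repeat a simple bending movement (stand upright, bend to
touch a target, return) while a small IMU on the sacrum records three
acceleration channels (AccX/AccY/AccZ, in g) and three angular-velocity
channels (GyrX/GyrY/GyrZ, in °/s) at 100 Hz, and to compute the **Sample
Entropy** (SampEn) of those time series.  `trunkentropy` implements the full
analysis chain for such recordings, plus a synthetic-recording generator so
every stage can be tested against known ground truth.

## The statistic at the core

For a series *x₁ … x_N*, embedding dimension *m* and tolerance *r*, with
templates *uᵢ = (xᵢ, …, xᵢ₊ₘ₋₁)* for *i = 1 … N − m*:

* *B* = number of ordered pairs (i, j), i ≠ j, with Chebyshev distance
  d(uᵢ, uⱼ) ≤ r at template length *m*;
* *A* = the same count at length *m + 1* (both counts over i, j ≤ N − m,
  self-matches excluded);
* **SampEn = −ln(A/B)** — lower values mean a more regular, more
  predictable movement.

Defaults are the standard *m* = 2 and *r* = 0.2 × SD of the series
(population SD).  The production implementation (compiled, exhaustive pair
counting) is verified bit-exactly against an independent plain-R oracle,
`sampEnOracle()`.

Around the entropy core the package provides:

* `readRecording()` / `writeRecording()` — delimited-text recording I/O
  with a `#`-prefixed metadata sidecar block;
* `segmentTest()` — automatic trimming of the recording to the bending-cycle
  span, using the left–right-rotation marker the protocol places before the
  first cycle;
* `integrateGyro()` / `detectCycles()` / `velocitySds()` — angular amplitude
  per cycle by gyroscope integration (with linear drift removal), and the
  SDX/SDY/SDZ variability descriptors;
* `sampEn50()` / `sampEnPartials()` — entropy of the full test and of
  growing windows [10 s, I s), I = 12, 14, …, 70 s;
* `regressThroughOrigin()` / `selectDuration()` / `blandAltman()` /
  `compareConditions()` / `crossConditionCorrelation()` — the agreement
  layer that selects the shortest clinically feasible test duration
  (smallest I with R² > 0.99 and slope k > 0.95) and quantifies agreement
  between the shortened and the full test;
* `simulateRecording()` / `simulateCohort()` — synthetic recordings with a
  controllable complexity knob (AR(1) sensor-noise SD) and stored ground
  truth;
* `runPipeline()` — the end-to-end cohort driver producing a
  machine-readable report.

## Worked example

```r
library(trunkentropy)

rec <- simulateRecording(participantParams(meanAmplitude = 30), seed = 42)
rec
#> IMURecording: 10881 samples x 6 channels @ 100 Hz (108.81 s)
#>   participant: sim  condition: stool

trimmed <- segmentTest(rec)          # locate the 50-cycle test span
trimmed$GyrX
#> TrimmedSeries GyrX: 10229 samples @ 100 Hz, span [452, 10681)

cycles <- detectCycles(integrateGyro(trimmed$GyrX))
cycles
#> CycleAmplitudes: 50 cycles, mean amplitude 30.06 deg (range 26.20-32.57)

round(velocitySds(trimmed), 2)
#>   sdX   sdY   sdZ
#> 32.86  2.01  3.86

sampEn(trimmed$GyrX)
#> SampEn = 0.1090 nats (A=1.10262e+07, B=1.22966e+07, N=10229), m=2,
#> r=0.2 (relative, abs 6.572)

head(sampEnPartials(trimmed$GyrX)[, c("I", "sampen", "n")])
#>    I sampen    n
#> 1 12 0.1254  200
#> 2 14 0.1176  400
#> 3 16 0.1103  600
#> ...
```

All 50 planted cycles are recovered, the mean amplitude matches the planted
30°, the sagittal channel GyrX carries most of the angular-velocity
variability (SDX ≫ SDY, SDZ), and its SampEn is low — the bending movement
is highly regular — with the partial-window values converging towards the
full-test value as the window grows.

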