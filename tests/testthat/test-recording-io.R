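test_that("write/read round-trips a recording", {
  rec <- simulateRecording(participantParams(nCycles = 5L),
                           participant = "P01", condition = "box", seed = 2)
  f <- tempfile(fileext = ".csv")
  writeRecording(rec, f)
  rec2 <- readRecording(f)
  expect_equal(imuChannels(rec2), imuChannels(rec), tolerance = 1e-12)
  expect_equal(samplingRate(rec2), samplingRate(rec), tolerance = 1e-6)
  expect_identical(imuMeta(rec2)$participant, "P01")
  expect_identical(imuMeta(rec2)$condition, "box")
  unlink(f)
})

test_that("rows with non-finite values are dropped and counted", {
  rec <- simulateRecording(participantParams(nCycles = 5L), seed = 3)
  f <- tempfile(fileext = ".csv")
  writeRecording(rec, f)
  lines <- readLines(f)
  hdr <- grep("^time", lines)
  bad <- hdr + c(50, 120, 200)
  for (i in bad) {
    fields <- strsplit(lines[i], ",")[[1]]
    fields[5] <- "NaN"  # GyrX column
    lines[i] <- paste(fields, collapse = ",")
  }
  writeLines(lines, f)
  expect_message(rec2 <- readRecording(f), "dropped 3 row")
  expect_identical(imuMeta(rec2)$droppedRows, 3L)
  expect_identical(nSamples(rec2), nSamples(rec) - 3L)
  unlink(f)
})

test_that("a 12,000-sample 100 Hz recording reports a 120.00 s duration", {
  set.seed(1)
  data <- matrix(rnorm(12000 * 6), ncol = 6,
                 dimnames = list(NULL, c("AccX", "AccY", "AccZ",
                                         "GyrX", "GyrY", "GyrZ")))
  rec <- new("IMURecording", data = data, time = (0:11999) / 100,
             samplingRate = 100, meta = list())
  expect_equal(duration(rec), 120.00)
})

test_that("missing columns and non-uniform sampling are reported", {
  rec <- simulateRecording(participantParams(nCycles = 5L), seed = 4)
  f <- tempfile(fileext = ".csv")
  writeRecording(rec, f)
  lines <- readLines(f)
  hdr <- grep("^time", lines)
  lines[hdr] <- sub("GyrZ", "other", lines[hdr])
  writeLines(lines, f)
  expect_error(readRecording(f), "GyrZ")
  # a renamed column is recoverable through the mapping option
  rec2 <- readRecording(f, columnMap = c(GyrZ = "other"))
  expect_equal(imuChannels(rec2)[, "GyrZ"], imuChannels(rec)[, "GyrZ"],
               tolerance = 1e-12)

  writeRecording(rec, f)
  lines <- readLines(f)
  i <- hdr + 100
  fields <- strsplit(lines[i], ",")[[1]]
  fields[1] <- as.character(as.numeric(fields[1]) + 0.004)  # 40% jitter
  lines[i] <- paste(fields, collapse = ",")
  writeLines(lines, f)
  expect_error(readRecording(f), "non-uniform sampling")
  unlink(f)
})

test_that("header matching is case-insensitive and separator-tolerant", {
  rec <- simulateRecording(participantParams(nCycles = 5L), seed = 5)
  f <- tempfile(fileext = ".csv")
  writeRecording(rec, f)
  lines <- readLines(f)
  hdr <- grep("^time", lines)
  lines[hdr] <- "Time,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z"
  writeLines(lines, f)
  rec2 <- readRecording(f)
  expect_equal(imuChannels(rec2), imuChannels(rec), tolerance = 1e-12)
  unlink(f)
})

test_that("segmentation finds the test onset near the ground truth", {
  for (s in 1:5) {
    rec <- simulateRecording(participantParams(nCycles = 20L), seed = 400 + s)
    gt <- imuMeta(rec)$groundTruth
    tr <- segmentTest(rec)
    sp <- trimSpan(tr$GyrX)
    expect_lt(abs(sp["start"] - gt$cycleStart) / samplingRate(rec), 0.25)
    expect_lt(abs(sp["end"] - gt$cycleEnd) / samplingRate(rec), 1.0)
    # identical span on every channel
    for (ch in names(tr)) expect_identical(trimSpan(tr[[ch]]), sp)
  }
})

test_that("segmentation degenerate inputs raise the documented errors", {
  rec <- simulateRecording(participantParams(nCycles = 10L), seed = 6)
  expect_error(segmentTest(rec, zeroTol = 100), "marker not detected")
})

test_that("a noiseless trim starts and ends at (near-)zero velocity", {
  rec <- noiselessRecording(nCycles = 10L)
  tr <- segmentTest(rec)
  v <- trimmedValues(tr$GyrX)
  expect_lte(abs(v[1]), 2)
  expect_lte(abs(v[length(v)]), 2)
})

test_that("trimming an already trimmed recording is the identity", {
  rec <- simulateRecording(participantParams(nCycles = 15L), seed = 7)
  tr <- segmentTest(rec)
  cut <- trimRecording(rec, tr)
  tr2 <- segmentTest(cut, markerChannel = NULL)
  sp2 <- trimSpan(tr2$GyrX)
  expect_identical(unname(sp2), c(0L, nSamples(cut)))
  expect_identical(trimmedValues(tr2$GyrX), trimmedValues(tr$GyrX))
})

test_that("segmentation recovers the planted cycle count across seeds", {
  hits <- 0L
  for (s in 1:10) {
    rec <- simulateRecording(participantParams(), seed = 600 + s)
    cyc <- detectCycles(integrateGyro(segmentTest(rec)$GyrX))
    if (nCycles(cyc) == 50L) hits <- hits + 1L
  }
  expect_gte(hits, 10L * 0.95)
})
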