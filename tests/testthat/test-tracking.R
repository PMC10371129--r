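test_that("the reference is the gated mean of the baseline pulses", {
  cfg <- smallConfig()
  rec <- simulateMeasurement(cfg, constantTrajectory(300), 0)
  ref <- buildReference(rec)
  # noise/jitter off: every baseline row is identical, so the reference
  # equals any row within the gate
  expect_equal(ref$reference, rec@alines[1, ref$gate])
  # centre coincides with the surface-echo round trip
  t <- cfg@recordStart + (ref$center - 1) / cfg@samplingRate
  expect_lt(abs(t - 2 * cfg@surfaceDepth / cfg@soundSpeed),
            0.5 / cfg@centerFrequency)
})

test_that("baseline averaging reduces jitter variance", {
  cfg <- smallConfig(amplitudeJitter = 0.05, nBaselinePulses = 16L)
  set.seed(5)
  rec <- simulateMeasurement(cfg, constantTrajectory(300), 0)
  ref <- buildReference(rec)
  bl <- rec@alines[rec@pulseRole == "baseline", ref$gate, drop = FALSE]
  clean <- synthesizeAline(smallConfig(), 0)[ref$gate]
  refErr <- mean((ref$reference - clean)^2)
  rowErr <- mean(apply(bl, 1, function(r) mean((r - clean)^2)))
  expect_lt(refErr, rowErr)
})

test_that("a single baseline pulse is its own reference; none is an error", {
  cfg <- smallConfig(nBaselinePulses = 1L)
  rec <- simulateMeasurement(cfg, constantTrajectory(300), 0)
  ref <- buildReference(rec)
  expect_equal(ref$reference, rec@alines[1, ref$gate])
  badRec <- rec
  badRec@pulseRole[1] <- "detection"  # no baseline rows left
  expect_error(buildReference(badRec), "baseline")
})

test_that("delay of an echo against itself is zero with unit correlation", {
  cfg <- smallConfig()
  ref <- synthesizeAline(cfg, 0)
  d <- estimateDelay(ref, ref, cfg@samplingRate)
  expect_equal(d$delay, 0)
  expect_equal(d$peak, 1, tolerance = 1e-12)
  expect_false(d$lowConfidence)
})

test_that("integer-sample shifts are recovered exactly", {
  cfg <- smallConfig()
  ref <- synthesizeAline(cfg, 0)
  for (s in c(-4L, -1L, 3L)) {
    echo <- ref
    if (s > 0) echo <- c(rep(0, s), ref[1:(length(ref) - s)])
    if (s < 0) echo <- c(ref[(1 - s):length(ref)], rep(0, -s))
    d <- estimateDelay(ref, echo, cfg@samplingRate)
    expect_equal(round(d$lagSamples), s)
    expect_equal(d$delay, s / cfg@samplingRate, tolerance = 0.02)
  }
})

test_that("integer-lag estimates match the brute-force oracle", {
  cfg <- smallConfig(noiseSnrDb = 25, amplitudeJitter = 0.05)
  maxLag <- 10L
  for (s in 1:20) {
    pair <- gatedPair(cfg, runif(1, -15e-6, 15e-6), s)
    oracle <- bruteForceNcc(pair$ref, pair$echo, maxLag)
    d <- estimateDelay(pair$ref, pair$echo, cfg@samplingRate,
                       searchWindow = maxLag / cfg@samplingRate)
    expect_equal(d$lagInteger, oracle$bestLag)
  }
})

test_that("a band-limited 2.5-sample shift is recovered within 0.1 sample", {
  cfg <- smallConfig()
  ref <- synthesizeAline(cfg, 0)
  echo <- fractionalShift(ref, 2.5)
  d <- estimateDelay(ref, echo, cfg@samplingRate)
  expect_lt(abs(d$lagSamples - 2.5), 0.1)
})

test_that("delay converts to signed displacement at half the sound speed", {
  expect_equal(delayToDisplacement(10e-9, 1480), 7.4e-6)
  expect_equal(delayToDisplacement(0, 1480), 0)
  expect_equal(delayToDisplacement(-10e-9, 1480), -7.4e-6)
  expect_error(delayToDisplacement(1e-9, -1), "soundSpeed")
})

test_that("zero programmed motion tracks to zero displacement", {
  cfg <- smallConfig()
  rec <- simulateMeasurement(cfg, constantTrajectory(300, amp = 1e-12), 0)
  tr <- trackMeasurement(rec)
  expect_lt(max(abs(displacement(tr))), 1e-8)  # < 10 nm
  expect_true(all(correlationPeak(tr) > 0.99))
})

test_that("a noise-free damped oscillation is recovered to sub-0.05 um RMS", {
  cfg <- acquisitionConfig(noiseSnrDb = Inf, amplitudeJitter = 0,
                           nChannels = 1L, nDetectionPulses = 200L)
  traj <- constantTrajectory(300)
  rec <- simulateMeasurement(cfg, traj, 0)
  tr <- trackMeasurement(rec)
  sTrue <- surfaceResponse(traj, 0, rec@tau)
  expect_lt(sqrt(mean((displacement(tr) - sTrue)^2)), 0.05e-6)
})

test_that("recovered displacement is linear in the programmed amplitude", {
  cfg <- smallConfig(nDetectionPulses = 128L)
  base <- NULL
  for (alpha in c(0.1, 0.5, 1, 2)) {
    traj <- constantTrajectory(300, amp = alpha * 10e-6)
    rec <- simulateMeasurement(cfg, traj, 0)
    tr <- trackMeasurement(rec)
    amp <- max(abs(displacement(tr)))
    if (alpha == 0.1) base <- amp / 0.1
    expect_equal(amp, alpha * base, tolerance = 0.01)
  }
})

test_that("tracking is robust to per-pulse amplitude jitter", {
  # identical acquisition with and without +/-5 % amplitude jitter: the
  # averaged-baseline + normalised-correlation chain must be insensitive
  traj <- constantTrajectory(300)
  set.seed(21)
  recJ <- simulateMeasurement(smallConfig(amplitudeJitter = 0.05,
                                          nDetectionPulses = 128L),
                              traj, 0)
  recN <- simulateMeasurement(smallConfig(nDetectionPulses = 128L), traj, 0)
  dJ <- displacement(trackMeasurement(recJ))
  dN <- displacement(trackMeasurement(recN))
  expect_lt(sqrt(mean((dJ - dN)^2)), 0.1e-6)
})

test_that("traces assemble into an observation-time-ordered matrix", {
  cfg <- smallConfig(totalDuration = 60, nDetectionPulses = 16L)
  run <- simulateRun(cfg, constantTrajectory(300))
  traces <- lapply(run@records[[1]], trackMeasurement)
  dm <- assembleMatrix(traces)
  expect_equal(nrow(displacement(dm)), 11)
  expect_equal(observationTimes(dm), seq(0, 60, by = 6))
  # shuffled input produces the identical matrix
  dm2 <- assembleMatrix(traces[sample(length(traces))])
  expect_identical(displacement(dm), displacement(dm2))
  # a missing measurement becomes a flagged NA gap row
  dm3 <- assembleMatrix(traces[-4], times = observationTimes(run))
  expect_true(dm3@gap[4])
  expect_true(all(is.na(displacement(dm3)[4, ])))
  expect_false(any(dm3@gap[-4]))
})

test_that("mixing channels in one matrix is an error", {
  cfg <- smallConfig(nDetectionPulses = 16L)
  t1 <- trackMeasurement(simulateMeasurement(cfg, constantTrajectory(300),
                                             0, channel = 1L))
  t2 <- trackMeasurement(simulateMeasurement(cfg, constantTrajectory(300),
                                             6, channel = 2L))
  expect_error(assembleMatrix(list(t1, t2)), "channels")
})
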