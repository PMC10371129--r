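test_that("a pure sinusoid peaks at its frequency", {
  tau <- (0:499) * 1e-4
  x <- sin(2 * pi * 300 * tau)
  ps <- powerSpectrum(x, dt = 1e-4)
  pk <- peakFrequency(ps)
  expect_lt(abs(pk$frequency - 300), 1 / (length(ps@power) * 2 * 1e-4))
  expect_equal(max(ps@power), 1)
  expect_false(ps@degenerate)
})

test_that("frequency grid step is 1/(nFft * dt)", {
  ps <- powerSpectrum(sin(2 * pi * 300 * (0:499) * 1e-4), nFft = 2048,
                      dt = 1e-4)
  expect_equal(ps@frequency[2] - ps@frequency[1], 1 / (2048 * 1e-4))
})

test_that("DC-only and all-zero traces give a flagged zero spectrum", {
  for (x in list(rep(0, 64), rep(3.2, 64))) {
    ps <- powerSpectrum(x, dt = 1e-4)
    expect_true(ps@degenerate)
    expect_true(all(ps@power == 0))
    pk <- peakFrequency(ps)
    expect_true(is.na(pk$frequency))
  }
  expect_error(powerSpectrum(rep(0, 4), dt = 1e-4), "8 samples")
})

test_that("halving the decay time broadens the -3 dB peak", {
  w <- vapply(c(20e-3, 10e-3, 2e-3), function(taud) {
    peakFrequency(powerSpectrum(dhoTrace(300, taud)))$width
  }, numeric(1))
  expect_true(all(diff(w) > 0))  # shorter decay -> wider peak, strictly
})

test_that("tied peak powers resolve to the lower frequency", {
  freq <- seq(0, 1000, by = 10)
  p <- rep(0, length(freq))
  p[freq == 250] <- 1
  p[freq == 620] <- 1
  ps <- new("PowerSpectrum", frequency = freq, power = p,
            observationTime = 0, degenerate = FALSE)
  expect_equal(peakFrequency(ps)$frequency, 250)
})

test_that("spectrogram columns are individually normalised", {
  cfg <- smallConfig(totalDuration = 36, nDetectionPulses = 128L)
  run <- simulateRun(cfg, coagulationTrajectory(tStart = 6, tEnd = 30))
  dm <- assembleMatrix(lapply(run@records[[1]], trackMeasurement))
  sp <- buildSpectrogram(dm)
  sg <- sp$spectrogram
  for (m in seq_along(observationTimes(sg)))
    if (!sg@degenerate[m]) expect_equal(max(sg@power[, m]), 1)
})

test_that("a constant-frequency run yields a flat frequency trace", {
  cfg <- smallConfig(totalDuration = 36, nDetectionPulses = 256L)
  run <- simulateRun(cfg, constantTrajectory(400))
  dm <- assembleMatrix(lapply(run@records[[1]], trackMeasurement))
  ft <- buildSpectrogram(dm)$trace
  f <- peakFrequencies(ft)
  dtau <- fastTime(dm)[2] - fastTime(dm)[1]
  res <- 1 / (1024 * dtau)
  expect_true(all(abs(f - 400) < res))
})

test_that("gap rows propagate as missing values, empty input stays empty", {
  cfg <- smallConfig(totalDuration = 24, nDetectionPulses = 64L)
  run <- simulateRun(cfg, constantTrajectory(400))
  traces <- lapply(run@records[[1]], trackMeasurement)
  dm <- assembleMatrix(traces[-2], times = observationTimes(run))
  sp <- buildSpectrogram(dm)
  expect_true(sp$spectrogram@degenerate[2])
  expect_true(is.na(peakFrequencies(sp$trace)[2]))
  expect_false(any(is.na(peakFrequencies(sp$trace)[-2])))

  empty <- new("DisplacementMatrix", channel = 1L,
               observationTimes = numeric(0), tau = numeric(0),
               displacement = matrix(numeric(0), 0, 0),
               correlationPeak = matrix(numeric(0), 0, 0),
               gap = logical(0))
  out <- buildSpectrogram(empty)
  expect_length(observationTimes(out$trace), 0)
  expect_length(out$spectrogram@frequency, 0)
})

test_that("noiseless frequency sweep is recovered within one bin and monotone", {
  fTrue <- seq(150, 1950, by = 150)
  dt <- 1e-4
  fHat <- vapply(fTrue, function(f) {
    tr <- dhoTrace(f, taud = max(20e-3, 5 / f))
    peakFrequency(powerSpectrum(tr, nFft = 2048))$frequency
  }, numeric(1))
  expect_true(all(abs(fHat - fTrue) <= max(1 / (2048 * dt), 5)))
  expect_true(all(diff(fHat) > 0))
})
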