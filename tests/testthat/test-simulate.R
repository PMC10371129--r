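test_that("trajectory curves plateau exactly and transition monotonically", {
  for (shape in c("sigmoid", "piecewise_linear")) {
    traj <- coagulationTrajectory(tStart = 90, tEnd = 150, shape = shape)
    T <- seq(0, 400, by = 2)
    f <- trajectoryFrequency(traj, T)
    expect_true(all(f[T <= 90] == traj@fLiquid))
    expect_true(all(f[T >= 150] == traj@fSolid))
    expect_true(all(diff(f) >= 0))
    A <- trajectoryAmplitude(traj, T)
    expect_true(all(A[T <= 90] == traj@ampLiquid))
    expect_true(all(A[T >= 150] == traj@ampSolid))
    expect_true(all(diff(A) <= 0))
  }
  never <- constantTrajectory(300)
  expect_true(all(trajectoryFrequency(never, seq(0, 3600, 60)) == 300))
})

test_that("surface response is a damped sinusoid with the programmed envelope", {
  traj <- coagulationTrajectory(tStart = 90, tEnd = 150)
  expect_equal(surfaceResponse(traj, 0, 0), 0)  # sine at phase zero
  tau <- seq(0, 0.05, by = 1e-4)
  s <- surfaceResponse(traj, 0, tau)
  A <- traj@ampLiquid
  expect_true(all(abs(s) <= A * exp(-tau / traj@decayLiquid) + 1e-15))
  # envelope at tau = decay time is 1/e of the amplitude
  taud <- traj@decayLiquid
  peakPhaseTau <- (floor(taud * traj@fLiquid) + 0.25) / traj@fLiquid
  expect_equal(abs(surfaceResponse(traj, 0, peakPhaseTau)),
               A * exp(-peakPhaseTau / taud), tolerance = 1e-6)
  expect_error(surfaceResponse(traj, 0, -1e-4), "tau")
})

test_that("synthesised A-line places the surface echo at the round-trip delay", {
  cfg <- smallConfig()
  tr0 <- synthesizeAline(cfg, 0)
  t <- cfg@recordStart + (seq_along(tr0) - 1) / cfg@samplingRate
  # strongest sample sits at the expected round trip within half a cycle
  expect_lt(abs(t[which.max(abs(tr0))] -
                2 * cfg@surfaceDepth / cfg@soundSpeed),
            0.5 / cfg@centerFrequency)
  # 7.4 um displacement -> +10 ns delay -> a shift the correlation sees
  trUp <- synthesizeAline(cfg, 7.4e-6)
  d <- estimateDelay(tr0, trUp, cfg@samplingRate)
  expect_equal(d$delay, 10e-9, tolerance = 0.15)
  expect_error(synthesizeAline(cfg, 5e-3), "record window")
})

test_that("noise-free synthesis is deterministic and noisy synthesis is seeded", {
  cfg <- smallConfig()
  expect_identical(synthesizeAline(cfg, 1e-6), synthesizeAline(cfg, 1e-6))
  cfgN <- smallConfig(noiseSnrDb = 30, amplitudeJitter = 0.05)
  set.seed(11); a <- synthesizeAline(cfgN, 1e-6)
  set.seed(11); b <- synthesizeAline(cfgN, 1e-6)
  expect_identical(a, b)
  set.seed(12)
  expect_false(identical(a, synthesizeAline(cfgN, 1e-6)))
})

test_that("measurement records have the documented pulse structure", {
  cfg <- smallConfig()
  rec <- simulateMeasurement(cfg, constantTrajectory(300), 0)
  expect_s4_class(rec, "RarMeasurement")
  expect_equal(nrow(alines(rec)),
               cfg@nBaselinePulses + cfg@nDetectionPulses)
  expect_equal(pulseRole(rec),
               rep(c("baseline", "detection"),
                   c(cfg@nBaselinePulses, cfg@nDetectionPulses)))
  expect_equal(rec@tau, (0:(cfg@nDetectionPulses - 1)) / cfg@prf)
})

test_that("simulated runs share a synchronised observation grid", {
  cfg <- smallConfig(totalDuration = 60, nChannels = 3L,
                     nDetectionPulses = 16L)
  run <- simulateRun(cfg, coagulationTrajectory(tStart = 20, tEnd = 40))
  expect_equal(length(observationTimes(run)), 11)  # T = 0, 6, ..., 60
  expect_equal(observationTimes(run), seq(0, 60, by = 6))
  for (ch in 1:3) {
    Ts <- vapply(run@records[[ch]], function(r) r@observationTime,
                 numeric(1))
    expect_equal(Ts, observationTimes(run))
  }
})

test_that("identical seeds reproduce a run bit-identically", {
  cfg <- smallConfig(totalDuration = 24, noiseSnrDb = 30,
                     amplitudeJitter = 0.05, nDetectionPulses = 16L)
  traj <- coagulationTrajectory(tStart = 6, tEnd = 18)
  r1 <- simulateRun(cfg, traj, seed = 99)
  r2 <- simulateRun(cfg, traj, seed = 99)
  expect_identical(r1@records, r2@records)
  r3 <- simulateRun(cfg, traj, seed = 100)
  expect_false(identical(r1@records, r3@records))
})

test_that("a never-clotting channel has constant ground-truth frequency", {
  cfg <- smallConfig(totalDuration = 60, nDetectionPulses = 16L)
  run <- simulateRun(cfg, constantTrajectory(54.7))
  expect_true(all(run@truth[[1]]$fTrue == 54.7))
  expect_true("no_clot" %in% run@truth[[1]]$params@flags)
})

test_that("analytic parameter truth matches hand-applied threshold rules", {
  # piecewise-linear ramp 100 -> 200 Hz over [60, 120] s, 6 s grid, 420 s:
  # f_int = 100 (all samples in the first minute are pre-transition);
  # f_end = 200 (window [120, 420] is entirely post-transition);
  # 1.05*f_int = 105 first reached at T = 66 (f = 110);
  # 0.95*f_end = 190 first reached at T = 114 (f = 190).
  cfg <- smallConfig(totalDuration = 420)
  traj <- coagulationTrajectory(fLiquid = 100, fSolid = 200, tStart = 60,
                                tEnd = 120, shape = "piecewise_linear")
  p <- groundTruthParams(cfg, traj)
  expect_equal(p@fInt, 100)
  expect_equal(p@fEnd, 200)
  expect_equal(p@tInt, 66)
  expect_equal(p@tEnd, 114)
  expect_equal(p@duration, 48)
  expect_length(p@flags, 0)
})

test_that("physical consistency: programmed displacement equals c/2 x delay shift", {
  cfg <- smallConfig()
  disp <- 12e-6
  delayShift <- 2 * disp / cfg@soundSpeed
  expect_equal(delayToDisplacement(delayShift, cfg@soundSpeed), disp)
})
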