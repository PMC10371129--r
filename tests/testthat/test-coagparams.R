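grid6 <- function(n, from = 0) seq(from, by = 6, length.out = n)

test_that("initial frequency averages only the first minute", {
  tr <- freqTrace(grid6(101), rep(300, 101))
  expect_equal(initialFrequency(tr), 300)
  # step to 400 Hz after T = 60 s is excluded from the window
  f <- ifelse(grid6(101) <= 60, 300, 400)
  expect_equal(initialFrequency(freqTrace(grid6(101), f)), 300)
  # 11 samples alternating 299/301 starting at 299
  alt <- rep(c(299, 301), length.out = 11)
  expect_equal(initialFrequency(freqTrace(grid6(11), alt)),
               299.9090909091, tolerance = 1e-10)
})

test_that("final frequency averages the last five minutes", {
  tr <- freqTrace(grid6(101), rep(520, 101))
  expect_equal(finalFrequency(tr), 520)
  # plateau at 520 for the final 6 min of a longer trace
  times <- grid6(151)  # 0..900 s
  f <- ifelse(times >= 540, 520, 300)
  expect_equal(finalFrequency(freqTrace(times, f)), 520)
  # linear ramp 100 -> 200 Hz over 0..600 s: window [300, 600] holds
  # 150..200 in steps of 1, mean 175
  times <- grid6(101)
  ramp <- 100 + times / 6
  expect_equal(finalFrequency(freqTrace(times, ramp)), 175)
})

test_that("clotting start applies the 5 % threshold with persistence", {
  # hand-worked case: f_int = 300, threshold 315; samples 312 (T=126),
  # 324 (T=132), 330 (T=138) -> first sustained crossing at T = 132
  times <- grid6(24)          # 0 .. 138
  f <- c(rep(300, 21), 312, 324, 330)
  expect_equal(clottingStart(freqTrace(times, f), fInt = 300), 132)
  # constant trace never crosses
  expect_true(is.na(clottingStart(freqTrace(grid6(24), rep(300, 24)), 300)))
  # a single spike above threshold followed by a sub-threshold sample is
  # not a crossing
  fs <- rep(300, 24); fs[10] <- 340
  expect_true(is.na(clottingStart(freqTrace(grid6(24), fs), 300)))
  # missing values are skipped, never treated as crossings
  fm <- c(rep(300, 20), NA, 324, NA, 330)
  expect_equal(clottingStart(freqTrace(times, fm), 300), 126)
  expect_error(clottingStart(freqTrace(times, f), fInt = -1), "fInt")
})

test_that("clotting end applies the 95 % threshold", {
  times <- grid6(24)
  f <- c(rep(300, 20), 360, 475, 490, 495)
  # f_end = 500 -> threshold 475, first sustained at T = 126
  expect_equal(clottingEnd(freqTrace(times, f), fEnd = 500), 126)
  # trace already above threshold at the first sample
  expect_equal(clottingEnd(freqTrace(times, rep(480, 24)), 500), 0)
})

test_that("extractParams composes the parameters with exact duration", {
  # noiseless sigmoid trace on the observation grid; compare against the
  # independent analytic oracle
  cfg <- smallConfig(totalDuration = 900)
  traj <- coagulationTrajectory(fLiquid = 54.7, fSolid = 265,
                                tStart = 120, tEnd = 300)
  times <- seq(0, 900, by = 6)
  tr <- freqTrace(times, trajectoryFrequency(traj, times))
  truth <- groundTruthParams(cfg, traj)
  for (mf in c(TRUE, FALSE)) {  # monotone trace: filter must not matter
    p <- extractParams(tr, medianFilter = mf)
    expect_equal(p@fInt, truth@fInt)
    expect_equal(p@fEnd, truth@fEnd)
    expect_equal(p@tInt, truth@tInt)
    expect_equal(p@tEnd, truth@tEnd)
    expect_equal(p@duration, p@tEnd - p@tInt)
  }
})

test_that("flat and truncated traces are flagged, never errors", {
  pFlat <- extractParams(freqTrace(grid6(101), rep(300, 101)))
  expect_true("no_clot" %in% pFlat@flags)
  expect_true(is.na(pFlat@tInt))
  expect_true(is.na(pFlat@duration))
  # 4-minute run: truncated, best-effort values still reported
  times <- grid6(41)  # 0..240 s
  f <- ifelse(times < 120, 300, 400)
  pTr <- extractParams(freqTrace(times, f))
  expect_true("truncated" %in% pTr@flags)
  expect_true(is.finite(pTr@fInt) && is.finite(pTr@fEnd))
  # near-degenerate rise (< 5 %) is classified no_clot
  f2 <- ifelse(times < 120, 300, 309)
  expect_true("no_clot" %in% extractParams(freqTrace(times, f2))@flags)
  # mostly-missing trace is low confidence
  f3 <- rep(NA_real_, 101); f3[1:10] <- 300
  expect_true("low_confidence" %in%
                extractParams(freqTrace(grid6(101), f3))@flags)
})

test_that("ordering and grid quantisation hold across random trajectories", {
  cfg <- smallConfig(totalDuration = 900)
  times <- seq(0, 900, by = 6)
  set.seed(42)
  for (i in 1:25) {
    ts <- sort(runif(2, 60, 600))
    if (diff(ts) < 12) ts[2] <- ts[1] + 12
    traj <- coagulationTrajectory(fLiquid = 54.7, fSolid = 265,
                                  tStart = ts[1], tEnd = ts[2])
    f <- trajectoryFrequency(traj, times) * (1 + rnorm(length(times), 0, 5e-3))
    p <- extractParams(freqTrace(times, f))
    if (!"no_clot" %in% p@flags) {
      expect_lte(p@tInt, p@tEnd)
      expect_true(p@tInt %in% times)
      expect_true(p@tEnd %in% times)
      expect_equal(p@duration, p@tEnd - p@tInt)
    }
  }
})

test_that("delaying the programmed onset delays the recovered T_int in step", {
  cfg <- smallConfig(totalDuration = 900)
  times <- seq(0, 900, by = 6)
  base <- NULL
  for (delta in c(0, 30, 60, 120)) {
    traj <- coagulationTrajectory(fLiquid = 54.7, fSolid = 265,
                                  tStart = 120 + delta, tEnd = 300 + delta)
    p <- extractParams(freqTrace(times, trajectoryFrequency(traj, times)))
    if (delta == 0) base <- p@tInt
    expect_lte(abs(p@tInt - (base + delta)), 6)
  }
})
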