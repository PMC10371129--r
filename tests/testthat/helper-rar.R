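# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no stored data.

# compact acquisition for fast unit tests (full-size settings are exercised
# in the acceptance tests)
smallConfig <- function(...) {
  args <- utils::modifyList(
    list(samplingRate = 20e6, nBaselinePulses = 4L,
         nDetectionPulses = 64L, totalDuration = 60, nChannels = 1L,
         noiseSnrDb = Inf, amplitudeJitter = 0),
    list(...))
  do.call(acquisitionConfig, args)
}

# a trajectory frozen in one state (tStart = Inf: the transition never
# happens, so the "liquid" slots define the state)
constantTrajectory <- function(f, amp = 20e-6, decay = 20e-3) {
  new("CoagulationTrajectory", fLiquid = f, fSolid = f + 1,
      tStart = Inf, tEnd = Inf, shape = "sigmoid",
      ampLiquid = amp, ampSolid = amp, decayLiquid = decay,
      decaySolid = decay)
}

# damped-harmonic-oscillator displacement trace built directly (no RF
# synthesis) for spectral-module tests
dhoTrace <- function(f, taud, A = 20e-6, n = 500L, dt = 1e-4, Tobs = 0) {
  tau <- (seq_len(n) - 1) * dt
  new("DisplacementTrace", channel = 1L, observationTime = Tobs,
      tau = tau, displacement = A * exp(-tau / taud) * sin(2 * pi * f * tau),
      correlationPeak = rep(1, n), lowConfidence = rep(FALSE, n))
}

# frequency trace straight from numbers
freqTrace <- function(times, f, width = NA_real_, power = 1) {
  n <- length(times)
  new("FrequencyTrace", observationTimes = times, peakFrequency = f,
      peakWidth = rep(width, n), peakPower = rep(power, n))
}

# Independent brute-force normalised cross-correlation oracle: plain R
# loops over every integer lag, same zero-padding semantics as the package
# kernel but sharing no code with it.
bruteForceNcc <- function(reference, echo, maxLag) {
  L <- length(reference)
  if (length(echo) == L) echo <- c(rep(0, maxLag), echo, rep(0, maxLag))
  stopifnot(length(echo) == L + 2 * maxLag)
  lags <- -maxLag:maxLag
  cc <- numeric(length(lags))
  refN <- sqrt(sum(reference^2))
  for (j in seq_along(lags)) {
    seg <- echo[(maxLag + lags[j] + 1):(maxLag + lags[j] + L)]
    den <- refN * sqrt(sum(seg^2))
    cc[j] <- if (den > 0) sum(seg * reference) / den else 0
  }
  list(lags = lags, cc = cc, bestLag = lags[which.max(cc)])
}

# gated reference + gated-wide echo pair from a synthesised measurement
gatedPair <- function(config, displacement, seedVal) {
  set.seed(seedVal)
  ref <- synthesizeAline(config, 0)
  echo <- synthesizeAline(config, displacement)
  list(ref = ref, echo = echo)
}
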