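# Multichannel acquisition simulator.
#
# Emulates the mRAR pulse sequence: per measurement, nBaselinePulses
# pulse-echo detections of the resting surface, a push tone burst, then
# nDetectionPulses pulse-echo detections at the PRF while the surface rings
# down as a damped harmonic oscillator. Each A-line contains two fixed
# well-plate interface echoes and the air-sample surface echo (the
# strongest: near-total reflection at the air interface), all modelled as
# Gaussian-windowed tone bursts at the centre frequency. Surface motion
# enters as a round-trip delay shift 2*displacement/soundSpeed of the
# surface echo; per-pulse multiplicative amplitude jitter and white noise
# emulate instrument variability.

# transition fraction g(T) in [0, 1]: 0 while liquid, 1 once clotted
.rampFraction <- function(trajectory, T) {
  if (is.infinite(trajectory@tStart)) return(rep(0, length(T)))
  t0 <- trajectory@tStart
  t1 <- trajectory@tEnd
  if (trajectory@shape == "piecewise_linear") {
    g <- (T - t0) / (t1 - t0)
  } else {
    # logistic with midpoint (t0+t1)/2 and width (t1-t0)/8, rescaled so the
    # plateaus are reached exactly at t0 and t1 (a raw logistic never is)
    m <- (t0 + t1) / 2
    w <- (t1 - t0) / 8
    graw <- stats::plogis((T - m) / w)
    glo <- stats::plogis((t0 - m) / w)
    ghi <- stats::plogis((t1 - m) / w)
    g <- (graw - glo) / (ghi - glo)
  }
  g[T <= t0] <- 0
  g[T >= t1] <- 1
  pmin(pmax(g, 0), 1)
}

#' Evaluate a coagulation trajectory over observation time
#'
#' `trajectoryFrequency()`, `trajectoryAmplitude()` and `trajectoryDecay()`
#' return the programmed resonant frequency (Hz), oscillation amplitude (m)
#' and ring-down decay time (s) at observation times `T`. All three
#' interpolate between their liquid and solid values with the trajectory's
#' transition shape; the frequency curve is non-decreasing and equals
#' `fLiquid` for `T <= tStart` and `fSolid` for `T >= tEnd` exactly.
#'
#' @param trajectory a [CoagulationTrajectory-class]
#' @param T observation time(s), s
#' @return numeric vector matching `T`
#' @export
trajectoryFrequency <- function(trajectory, T) {
  g <- .rampFraction(trajectory, T)
  (1 - g) * trajectory@fLiquid + g * trajectory@fSolid
}

#' @rdname trajectoryFrequency
#' @export
trajectoryAmplitude <- function(trajectory, T) {
  g <- .rampFraction(trajectory, T)
  (1 - g) * trajectory@ampLiquid + g * trajectory@ampSolid
}

#' @rdname trajectoryFrequency
#' @export
trajectoryDecay <- function(trajectory, T) {
  g <- .rampFraction(trajectory, T)
  (1 - g) * trajectory@decayLiquid + g * trajectory@decaySolid
}

#' Surface displacement of the ringing sample surface
#'
#' The surface responds to the push as a damped harmonic oscillator:
#' `S(T, tau) = A(T) * exp(-tau / tau_d(T)) * sin(2 pi f(T) tau)`, with
#' amplitude `A`, decay time `tau_d` and frequency `f` evaluated from the
#' coagulation trajectory at observation time `T`.
#'
#' @param trajectory a [CoagulationTrajectory-class]
#' @param T observation time, s (scalar)
#' @param tau fast time(s) since the push, s; must be `>= 0`
#' @return displacement in metres, one value per `tau`
#' @export
#' @examples
#' traj <- coagulationTrajectory(tStart = 90, tEnd = 150)
#' surfaceResponse(traj, 0, seq(0, 0.05, by = 1e-4))
surfaceResponse <- function(trajectory, T, tau) {
  stopifnot(length(T) == 1L)
  if (any(tau < 0)) stop("'tau' must be >= 0", call. = FALSE)
  A <- trajectoryAmplitude(trajectory, T)
  f <- trajectoryFrequency(trajectory, T)
  taud <- trajectoryDecay(trajectory, T)
  A * exp(-tau / taud) * sin(2 * pi * f * tau)
}

# Gaussian envelope std dev (s) from the -6 dB fractional bandwidth of the
# amplitude spectrum: fractional width fbw*fc = 2*sqrt(2 ln 2) * sigma_f
.pulseSigmaT <- function(config) {
  sigmaF <- config@fractionalBandwidth * config@centerFrequency /
    (2 * sqrt(2 * log(2)))
  1 / (2 * pi * sigmaF)
}

# record-window time grid
.recordTimes <- function(config) {
  n <- round(config@recordDuration * config@samplingRate)
  config@recordStart + (seq_len(n) - 1) / config@samplingRate
}

# A-line matrix for a vector of per-pulse surface displacements (m). Draws
# per-pulse amplitude jitter then white noise from the caller's RNG stream,
# in that order.
.alineMatrix <- function(config, displacements) {
  t <- .recordTimes(config)
  n <- length(t)
  P <- length(displacements)
  sigt <- .pulseSigmaT(config)
  fc <- config@centerFrequency
  wave <- function(dt) exp(-dt^2 / (2 * sigt^2)) * cos(2 * pi * fc * dt)

  plate <- rep(0, n)
  for (j in seq_along(config@plateDepths))
    plate <- plate + config@plateAmplitudes[j] *
      wave(t - 2 * config@plateDepths[j] / config@soundSpeed)

  t0 <- 2 * (config@surfaceDepth + displacements) / config@soundSpeed
  guard <- 3 * sigt
  if (any(t0 - guard < t[1]) || any(t0 + guard > t[n]))
    stop("surface-echo delay falls outside the record window; ",
         "extend recordStart/recordDuration", call. = FALSE)

  M <- matrix(plate, nrow = P, ncol = n, byrow = TRUE)
  # evaluate the moving surface echo only on its support (+/- 4.5 sigma)
  lo <- max(1L, floor((min(t0) - 4.5 * sigt - t[1]) * config@samplingRate) + 1L)
  hi <- min(n, ceiling((max(t0) + 4.5 * sigt - t[1]) * config@samplingRate) + 1L)
  dt <- outer(-t0, t[lo:hi], "+")
  M[, lo:hi] <- M[, lo:hi, drop = FALSE] + wave(dt)

  if (config@amplitudeJitter > 0) {
    jit <- 1 + stats::runif(P, -config@amplitudeJitter,
                            config@amplitudeJitter)
    M <- M * jit
  }
  if (is.finite(config@noiseSnrDb)) {
    sd <- 10^(-config@noiseSnrDb / 20)   # surface echo amplitude is 1
    M <- M + matrix(stats::rnorm(P * n, 0, sd), P, n)
  }
  M
}

#' Synthesise a single RF A-line
#'
#' Builds one digitised pulse-echo trace containing the fixed well-plate
#' interface echoes and the sample-surface echo (a Gaussian-windowed tone
#' burst at the centre frequency) whose round-trip delay is
#' `2 * (surfaceDepth + displacement) / soundSpeed`, plus per-pulse
#' amplitude jitter and white Gaussian noise per the configuration. Uses
#' the R random number generator; seed it for reproducibility. Positive
#' displacement means the surface moved away from the transducer (longer
#' round trip).
#'
#' @param config an [AcquisitionConfig-class]
#' @param displacement surface displacement from equilibrium, m (scalar)
#' @return numeric RF trace on the record-window sample grid
#' @export
#' @examples
#' cfg <- acquisitionConfig(noiseSnrDb = Inf, amplitudeJitter = 0)
#' trace <- synthesizeAline(cfg, 0)
synthesizeAline <- function(config, displacement) {
  stopifnot(length(displacement) == 1L)
  drop(.alineMatrix(config, displacement))
}

#' Simulate one RAR measurement of one channel
#'
#' Emits the full A-line matrix of a single measurement at observation time
#' `T`: `nBaselinePulses` baseline pulses of the resting surface followed by
#' `nDetectionPulses` detection pulses sampling the damped surface
#' oscillation programmed by the trajectory at fast times
#' `tau_n = n / prf`, `n = 0, 1, ...`. Uses the R random number generator.
#'
#' @param config an [AcquisitionConfig-class]
#' @param trajectory a [CoagulationTrajectory-class]
#' @param T observation time, s
#' @param channel channel index recorded in the measurement
#' @return a [RarMeasurement-class]
#' @export
simulateMeasurement <- function(config, trajectory, T, channel = 1L) {
  nb <- config@nBaselinePulses
  nd <- config@nDetectionPulses
  tau <- (seq_len(nd) - 1) / config@prf
  s <- surfaceResponse(trajectory, T, tau)
  disp <- c(rep(0, nb), s)
  new("RarMeasurement", channel = as.integer(channel), observationTime = T,
      alines = .alineMatrix(config, disp),
      pulseRole = rep(c("baseline", "detection"), c(nb, nd)),
      tau = tau, config = config)
}

# Analytic coagulation-parameter truth: the threshold definitions applied
# directly to the noiseless frequency trajectory on the observation grid.
# Deliberately a standalone implementation (not a call into the extraction
# code) so it can serve as an independent oracle.
.groundTruthParams <- function(trajectory, config, channel = NA_integer_) {
  Tm <- .observationGrid(config)
  f <- trajectoryFrequency(trajectory, Tm)
  flags <- character()
  if (max(Tm) - min(Tm) < 60 || max(Tm) - min(Tm) < 300)
    flags <- c(flags, "truncated")
  fInt <- mean(f[Tm <= Tm[1] + 60])
  fEnd <- mean(f[Tm >= Tm[length(Tm)] - 300])
  crossing <- function(threshold) {
    idx <- which(f >= threshold)
    for (i in idx) {
      if (i == length(f) || f[i + 1] >= threshold) return(Tm[i])
    }
    NA_real_
  }
  tInt <- tEnd <- dur <- NA_real_
  if (fEnd < 1.05 * fInt) {
    flags <- c(flags, "no_clot")
  } else {
    tInt <- crossing(1.05 * fInt)
    tEnd <- crossing(0.95 * fEnd)
    if (is.na(tInt) || is.na(tEnd)) {
      flags <- c(flags, "no_clot")
      tInt <- tEnd <- NA_real_
    } else {
      tEnd <- max(tEnd, tInt)
      dur <- tEnd - tInt
    }
  }
  new("CoagulationParams", channel = channel, fInt = fInt, fEnd = fEnd,
      tInt = tInt, tEnd = tEnd, duration = dur, flags = flags)
}

#' @rdname simulateRun
#' @export
groundTruthParams <- function(config, trajectory, channel = NA_integer_) {
  .groundTruthParams(trajectory, config, channel)
}

.observationGrid <- function(config) {
  m <- floor(config@totalDuration / config@measurementInterval)
  (0:m) * config@measurementInterval
}

#' Simulate a full multichannel RAR run
#'
#' Generates synchronised measurements for every channel at observation
#' times `T_m = m * measurementInterval`, `m = 0 ... floor(totalDuration /
#' measurementInterval)`, each channel following its own coagulation
#' trajectory. The returned run carries per-channel ground truth: the
#' noiseless frequency/amplitude curves on the observation grid and the
#' coagulation parameters obtained by applying the threshold definitions
#' analytically to the noiseless trajectory (`groundTruthParams()`).
#'
#' Identical `(config, trajectories, seed)` yield a bit-identical run.
#'
#' @param config an [AcquisitionConfig-class]
#' @param trajectories list of [CoagulationTrajectory-class], one per
#'   channel (a single trajectory is recycled to all channels)
#' @param seed integer seed (default: the config's seed)
#' @param channel for `groundTruthParams`, the channel index to record
#' @param trajectory for `groundTruthParams`, the channel's trajectory
#' @return a [RarRun-class]
#' @export
#' @examples
#' cfg <- acquisitionConfig(totalDuration = 60, nChannels = 1L,
#'                          nDetectionPulses = 64L, nBaselinePulses = 4L)
#' run <- simulateRun(cfg, list(coagulationTrajectory(tStart = 20, tEnd = 40)))
#' run
simulateRun <- function(config, trajectories = NULL, seed = config@seed) {
  nch <- config@nChannels
  if (is.null(trajectories)) trajectories <- list(coagulationTrajectory())
  if (is(trajectories, "CoagulationTrajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 1L && nch > 1L)
    trajectories <- rep(trajectories, nch)
  if (length(trajectories) != nch)
    stop("need one trajectory per channel", call. = FALSE)
  Tm <- .observationGrid(config)
  set.seed(as.integer(seed))
  records <- vector("list", nch)
  truth <- vector("list", nch)
  for (ch in seq_len(nch)) {
    traj <- trajectories[[ch]]
    records[[ch]] <- lapply(Tm, function(T)
      simulateMeasurement(config, traj, T, channel = ch))
    truth[[ch]] <- list(
      trajectory = traj,
      fTrue = trajectoryFrequency(traj, Tm),
      ampTrue = trajectoryAmplitude(traj, Tm),
      params = .groundTruthParams(traj, config, channel = as.integer(ch)))
  }
  new("RarRun", config = config, observationTimes = Tm, records = records,
      truth = truth)
}
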