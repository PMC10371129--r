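#' @import methods
NULL

# ---- geometry / material -----------------------------------------------

#' Well geometry and the resonant surface-wave wavenumber
#'
#' The resonant wavenumber of the surface wave in a cylindrical well is set
#' by the well radius and the resonant-mode constant: `k = z / a`, where `a`
#' is the radius and `z` the dimensionless mode constant. The default
#' `modeConstant = 3.8317` is the first nonzero root of the Bessel function
#' J1, i.e. the fundamental axisymmetric mode with a free-slip wall; other
#' mode conventions can be substituted via this parameter.
#'
#' @slot radius well radius in metres (default 3.25e-3, a 96-well plate well)
#' @slot modeConstant dimensionless resonant-mode constant
#' @aliases WellGeometry
#' @exportClass WellGeometry
setClass("WellGeometry",
  slots = c(radius = "numeric", modeConstant = "numeric"),
  prototype = prototype(radius = 3.25e-3, modeConstant = 3.8317))

setValidity("WellGeometry", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a single positive number")
  if (length(object@modeConstant) != 1L || !is.finite(object@modeConstant) ||
      object@modeConstant <= 0)
    return("modeConstant must be a single positive number")
  TRUE
})

#' @describeIn WellGeometry-class constructor
#' @param radius well radius (m)
#' @param modeConstant dimensionless resonant-mode constant
#' @return a `WellGeometry` object
#' @export
#' @examples
#' geom <- wellGeometry()
#' wavenumber(geom)  # 3.8317 / 3.25e-3
wellGeometry <- function(radius = 3.25e-3, modeConstant = 3.8317) {
  new("WellGeometry", radius = radius, modeConstant = modeConstant)
}

# ---- acquisition configuration -----------------------------------------

#' Acquisition configuration for one multichannel RAR run
#'
#' Holds every timing, geometry and acoustic constant of a multichannel
#' resonant-acoustic-rheometry acquisition. One RAR measurement consists of
#' `nBaselinePulses` pulse-echo detections of the equilibrium surface, one
#' push tone burst of `pushCycles` cycles at `centerFrequency` (20 us at the
#' defaults), and `nDetectionPulses` pulse-echo detections at pulse
#' repetition frequency `prf`; measurements repeat every
#' `measurementInterval` seconds for `totalDuration` seconds on `nChannels`
#' synchronised channels.
#'
#' @slot centerFrequency transducer centre frequency, Hz
#' @slot samplingRate digitiser sampling rate, Hz (>= 4 x centerFrequency)
#' @slot prf pulse repetition frequency of the detection pulses, Hz; the
#'   fast-time step is `1/prf`
#' @slot nBaselinePulses number of pre-push baseline detection pulses
#' @slot nDetectionPulses number of post-push detection pulses
#' @slot pushCycles cycles in the push tone burst
#' @slot measurementInterval observation-time step between RAR measurements, s
#' @slot totalDuration total monitored duration, s
#' @slot nChannels number of synchronised channels
#' @slot soundSpeed speed of sound in the coupling/sample path, m/s
#' @slot surfaceDepth equilibrium sample-surface distance from the
#'   transducer, m
#' @slot plateDepths depths of the fixed well-plate interface echoes, m
#' @slot plateAmplitudes relative amplitudes of the plate echoes (the
#'   air-sample surface echo has amplitude 1)
#' @slot recordStart start of the digitised record window, s after transmit
#' @slot recordDuration length of the digitised record window, s
#' @slot fractionalBandwidth -6 dB fractional bandwidth of the detection
#'   pulse (Gaussian envelope)
#' @slot noiseSnrDb white-noise SNR relative to the surface echo, dB
#'   (`Inf` disables noise)
#' @slot amplitudeJitter half-width of the per-pulse multiplicative
#'   amplitude jitter (0.05 = +/-5 %)
#' @slot seed integer seed controlling all simulator randomness
#' @aliases AcquisitionConfig
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  slots = c(
    centerFrequency   = "numeric",
    samplingRate      = "numeric",
    prf               = "numeric",
    nBaselinePulses   = "integer",
    nDetectionPulses  = "integer",
    pushCycles        = "integer",
    measurementInterval = "numeric",
    totalDuration     = "numeric",
    nChannels         = "integer",
    soundSpeed        = "numeric",
    surfaceDepth      = "numeric",
    plateDepths       = "numeric",
    plateAmplitudes   = "numeric",
    recordStart       = "numeric",
    recordDuration    = "numeric",
    fractionalBandwidth = "numeric",
    noiseSnrDb        = "numeric",
    amplitudeJitter   = "numeric",
    seed              = "integer"))

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  pos1 <- function(x) length(x) == 1L && is.finite(x) && x > 0
  if (!pos1(object@prf)) msg <- c(msg, "prf must be positive")
  if (!pos1(object@centerFrequency))
    msg <- c(msg, "centerFrequency must be positive")
  if (!pos1(object@samplingRate) ||
      object@samplingRate < 4 * object@centerFrequency)
    msg <- c(msg, "samplingRate must be >= 4 x centerFrequency")
  if (object@nDetectionPulses < 2L)
    msg <- c(msg, "nDetectionPulses must be >= 2")
  if (object@nBaselinePulses < 1L)
    msg <- c(msg, "nBaselinePulses must be >= 1")
  if (!pos1(object@measurementInterval))
    msg <- c(msg, "measurementInterval must be positive")
  if (!pos1(object@soundSpeed)) msg <- c(msg, "soundSpeed must be positive")
  if (!pos1(object@surfaceDepth)) msg <- c(msg, "surfaceDepth must be positive")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (length(object@plateDepths) != length(object@plateAmplitudes))
    msg <- c(msg, "plateDepths and plateAmplitudes lengths differ")
  if (any(object@plateDepths >= object@surfaceDepth))
    msg <- c(msg, "plate interfaces must be shallower than the sample surface")
  if (!pos1(object@recordDuration))
    msg <- c(msg, "recordDuration must be positive")
  if (object@fractionalBandwidth <= 0 || object@fractionalBandwidth >= 2)
    msg <- c(msg, "fractionalBandwidth must be in (0, 2)")
  if (object@amplitudeJitter < 0 || object@amplitudeJitter >= 1)
    msg <- c(msg, "amplitudeJitter must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn AcquisitionConfig-class constructor with the standard
#'   acquisition defaults (5 MHz centre frequency, 100 MHz sampling,
#'   10 kHz PRF, 20 baseline + 500 detection pulses, 100-cycle push,
#'   measurements every 6 s for 1 h on 4 channels, c = 1480 m/s).
#'   `recordStart`/`recordDuration` default to a window bracketing the
#'   plate and surface echoes.
#' @param centerFrequency,samplingRate,prf,nBaselinePulses,nDetectionPulses
#'   see slots
#' @param pushCycles,measurementInterval,totalDuration,nChannels see slots
#' @param soundSpeed,surfaceDepth,plateDepths,plateAmplitudes see slots
#' @param recordStart,recordDuration,fractionalBandwidth see slots
#' @param noiseSnrDb,amplitudeJitter,seed see slots
#' @return an `AcquisitionConfig` object
#' @export
#' @examples
#' cfg <- acquisitionConfig(totalDuration = 60, nChannels = 1L)
#' fastTimeStep(cfg)      # 1e-4 s
#' pushDuration(cfg)      # 2e-5 s (20 us)
acquisitionConfig <- function(centerFrequency = 5.0e6,
                              samplingRate = 100e6,
                              prf = 1.0e4,
                              nBaselinePulses = 20L,
                              nDetectionPulses = 500L,
                              pushCycles = 100L,
                              measurementInterval = 6.0,
                              totalDuration = 3600,
                              nChannels = 4L,
                              soundSpeed = 1480,
                              surfaceDepth = 12.9e-3,
                              plateDepths = surfaceDepth - c(4.0e-3, 3.0e-3),
                              plateAmplitudes = c(0.35, 0.45),
                              recordStart = 2 * (min(plateDepths) - 0.5e-3) / soundSpeed,
                              recordDuration = 2 * (surfaceDepth + 1.5e-3) / soundSpeed - recordStart,
                              fractionalBandwidth = 0.6,
                              noiseSnrDb = 30,
                              amplitudeJitter = 0.05,
                              seed = 1L) {
  new("AcquisitionConfig",
    centerFrequency = centerFrequency, samplingRate = samplingRate,
    prf = prf, nBaselinePulses = as.integer(nBaselinePulses),
    nDetectionPulses = as.integer(nDetectionPulses),
    pushCycles = as.integer(pushCycles),
    measurementInterval = measurementInterval,
    totalDuration = totalDuration, nChannels = as.integer(nChannels),
    soundSpeed = soundSpeed, surfaceDepth = surfaceDepth,
    plateDepths = plateDepths, plateAmplitudes = plateAmplitudes,
    recordStart = recordStart, recordDuration = recordDuration,
    fractionalBandwidth = fractionalBandwidth, noiseSnrDb = noiseSnrDb,
    amplitudeJitter = amplitudeJitter, seed = as.integer(seed))
}

# ---- coagulation trajectory --------------------------------------------

#' Programmable coagulation trajectory for the acquisition simulator
#'
#' Describes how the resonant surface wave of one sample evolves during
#' coagulation: resonant frequency rises from `fLiquid` (capillary regime)
#' to `fSolid` (Rayleigh regime) between `tStart` and `tEnd`, while the
#' oscillation amplitude falls from `ampLiquid` to `ampSolid` and the
#' ring-down decay time from `decayLiquid` to `decaySolid` (clot formation
#' damps the surface wave). The transition `shape` is either a clamped
#' logistic (`"sigmoid"`, midpoint `(tStart+tEnd)/2`, width
#' `(tEnd-tStart)/8`, rescaled so the plateaus are met exactly) or
#' `"piecewise_linear"`.
#'
#' @slot fLiquid,fSolid resonant frequencies of the liquid and clotted
#'   states, Hz (`fLiquid < fSolid`)
#' @slot tStart,tEnd transition start/end, s (`Inf` tStart = never clots)
#' @slot shape `"sigmoid"` or `"piecewise_linear"`
#' @slot ampLiquid,ampSolid surface oscillation amplitudes, m
#' @slot decayLiquid,decaySolid ring-down decay times, s
#' @aliases CoagulationTrajectory
#' @exportClass CoagulationTrajectory
setClass("CoagulationTrajectory",
  slots = c(fLiquid = "numeric", fSolid = "numeric",
            tStart = "numeric", tEnd = "numeric", shape = "character",
            ampLiquid = "numeric", ampSolid = "numeric",
            decayLiquid = "numeric", decaySolid = "numeric"))

setValidity("CoagulationTrajectory", function(object) {
  msg <- character()
  if (!(object@fLiquid > 0 && object@fSolid > object@fLiquid))
    msg <- c(msg, "need 0 < fLiquid < fSolid")
  if (!(object@tStart >= 0 &&
        (is.infinite(object@tStart) || object@tEnd > object@tStart)))
    msg <- c(msg, "need 0 <= tStart < tEnd (tStart = Inf: never clots)")
  if (!object@shape %in% c("sigmoid", "piecewise_linear"))
    msg <- c(msg, "shape must be 'sigmoid' or 'piecewise_linear'")
  if (!(object@ampLiquid > 0 && object@ampSolid > 0))
    msg <- c(msg, "amplitudes must be positive")
  if (!(object@decayLiquid > 0 && object@decaySolid > 0))
    msg <- c(msg, "decay times must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoagulationTrajectory-class constructor. Default frequencies
#'   correspond to plasma-like surface tension 0.072 N/m in the liquid state
#'   and shear modulus 1 kPa in the clotted state for the default well
#'   geometry; amplitudes and decay times reproduce the qualitative staging
#'   of a clotting plasma sample (large, long-ringing oscillation while
#'   liquid; small, heavily damped once clotted).
#' @param fLiquid,fSolid,tStart,tEnd,shape see slots
#' @param ampLiquid,ampSolid,decayLiquid,decaySolid see slots
#' @param geometry `WellGeometry` used for the frequency defaults
#' @param rho density (kg/m^3) used for the frequency defaults
#' @return a `CoagulationTrajectory` object
#' @export
#' @examples
#' traj <- coagulationTrajectory(tStart = 90, tEnd = 150)
#' trajectoryFrequency(traj, c(0, 90, 120, 150, 300))
coagulationTrajectory <- function(fLiquid = NULL, fSolid = NULL,
                                  tStart = 90, tEnd = 150,
                                  shape = c("sigmoid", "piecewise_linear"),
                                  ampLiquid = 20e-6, ampSolid = 2e-6,
                                  decayLiquid = 20e-3, decaySolid = 2e-3,
                                  geometry = wellGeometry(), rho = 1000) {
  shape <- match.arg(shape)
  k <- wavenumber(geometry)
  if (is.null(fLiquid)) fLiquid <- capillaryFrequency(0.072, rho, k)
  if (is.null(fSolid)) fSolid <- rayleighFrequency(1000, rho, k)
  new("CoagulationTrajectory",
    fLiquid = fLiquid, fSolid = fSolid, tStart = tStart, tEnd = tEnd,
    shape = shape, ampLiquid = ampLiquid, ampSolid = ampSolid,
    decayLiquid = decayLiquid, decaySolid = decaySolid)
}

# ---- measurement / run containers --------------------------------------

#' One RAR measurement: the A-line matrix of a single channel at one
#' observation time
#'
#' Rows are pulse-echo A-lines (baseline pulses first, then detection
#' pulses); columns are digitised samples on the record-window time grid.
#'
#' @slot channel channel index (1-based)
#' @slot observationTime observation (coagulation) time T of the
#'   measurement, s
#' @slot alines numeric matrix, `(nBaselinePulses + nDetectionPulses) x
#'   nSamples`
#' @slot pulseRole `"baseline"` or `"detection"` per row
#' @slot tau fast time of each detection pulse, s after the push
#' @slot config the `AcquisitionConfig` the record was acquired under
#' @aliases RarMeasurement
#' @exportClass RarMeasurement
setClass("RarMeasurement",
  slots = c(channel = "integer", observationTime = "numeric",
            alines = "matrix", pulseRole = "character", tau = "numeric",
            config = "AcquisitionConfig"))

setValidity("RarMeasurement", function(object) {
  msg <- character()
  nb <- object@config@nBaselinePulses
  nd <- object@config@nDetectionPulses
  if (nrow(object@alines) != nb + nd)
    msg <- c(msg, "alines must have nBaselinePulses + nDetectionPulses rows")
  if (length(object@pulseRole) != nrow(object@alines))
    msg <- c(msg, "pulseRole length must match alines rows")
  if (!all(object@pulseRole %in% c("baseline", "detection")))
    msg <- c(msg, "pulseRole entries must be 'baseline' or 'detection'")
  if (length(object@tau) != nd)
    msg <- c(msg, "tau must have one entry per detection pulse")
  if (nd > 1) {
    dtau <- diff(object@tau)
    if (any(dtau <= 0) ||
        max(abs(dtau - 1 / object@config@prf)) > 1e-9 / object@config@prf)
      msg <- c(msg, "tau must increase with constant step 1/prf")
  }
  if (length(msg)) msg else TRUE
})

#' A simulated (or imported) multichannel RAR run
#'
#' `records[[ch]][[m]]` is the `RarMeasurement` of channel `ch` at the m-th
#' observation time; all channels share the same observation-time grid
#' (synchronised acquisition). For simulated runs, `truth` holds per
#' channel the noiseless ground truth: the programmed trajectory, the
#' frequency/amplitude curves on the observation grid, and the coagulation
#' parameters obtained by applying the threshold definitions analytically.
#'
#' @slot config the `AcquisitionConfig`
#' @slot observationTimes shared observation-time grid, s
#' @slot records list (per channel) of lists of `RarMeasurement`
#' @slot truth list (per channel) of ground-truth lists (empty for
#'   imported data)
#' @aliases RarRun
#' @exportClass RarRun
setClass("RarRun",
  slots = c(config = "AcquisitionConfig", observationTimes = "numeric",
            records = "list", truth = "list"))

setValidity("RarRun", function(object) {
  if (length(object@records) != object@config@nChannels)
    return("records must have one element per channel")
  nT <- length(object@observationTimes)
  ok <- vapply(object@records, function(ch) length(ch) == nT, logical(1))
  if (!all(ok)) return("every channel must cover the observation-time grid")
  TRUE
})

# ---- tracking containers ------------------------------------------------

#' Surface-displacement trace of one RAR measurement
#'
#' The displacement of the sample surface versus fast time, recovered by
#' cross-correlating each detection echo against the averaged baseline
#' echo. `lowConfidence` flags fast-time samples whose correlation peak
#' fell below the confidence floor (value retained).
#'
#' @slot channel channel index
#' @slot observationTime observation time T, s
#' @slot tau fast-time grid, s
#' @slot displacement surface displacement per fast-time sample, m
#'   (positive = surface moving away from the transducer)
#' @slot correlationPeak normalised correlation peak per sample, in
#'   `[-1, 1]`
#' @slot lowConfidence logical flag per sample
#' @aliases DisplacementTrace
#' @exportClass DisplacementTrace
setClass("DisplacementTrace",
  slots = c(channel = "integer", observationTime = "numeric",
            tau = "numeric", displacement = "numeric",
            correlationPeak = "numeric", lowConfidence = "logical"))

setValidity("DisplacementTrace", function(object) {
  n <- length(object@tau)
  if (length(object@displacement) != n ||
      length(object@correlationPeak) != n ||
      length(object@lowConfidence) != n)
    return("tau, displacement, correlationPeak, lowConfidence lengths differ")
  cp <- object@correlationPeak[is.finite(object@correlationPeak)]
  if (length(cp) && (min(cp) < -1 - 1e-9 || max(cp) > 1 + 1e-9))
    return("correlationPeak must lie in [-1, 1]")
  TRUE
})

#' Two-time surface-displacement field S(T, tau) of one channel
#'
#' Rows are observation times (step = the measurement interval), columns the
#' fast-time grid. Missing measurements are kept as all-`NA` rows flagged in
#' `gap`, never interpolated.
#'
#' @slot channel channel index
#' @slot observationTimes strictly increasing observation-time grid, s
#' @slot tau fast-time grid, s
#' @slot displacement `length(observationTimes) x length(tau)` matrix, m
#' @slot correlationPeak matching matrix of correlation peaks
#' @slot gap logical per observation time: measurement missing
#' @aliases DisplacementMatrix
#' @exportClass DisplacementMatrix
setClass("DisplacementMatrix",
  slots = c(channel = "integer", observationTimes = "numeric",
            tau = "numeric", displacement = "matrix",
            correlationPeak = "matrix", gap = "logical"))

setValidity("DisplacementMatrix", function(object) {
  nT <- length(object@observationTimes)
  if (nT > 1 && any(diff(object@observationTimes) <= 0))
    return("observationTimes must be strictly increasing")
  if (!all(dim(object@displacement) == c(nT, length(object@tau))))
    return("displacement matrix dimensions inconsistent")
  if (!all(dim(object@correlationPeak) == dim(object@displacement)))
    return("correlationPeak matrix dimensions inconsistent")
  if (length(object@gap) != nT)
    return("gap must have one flag per observation time")
  TRUE
})

# ---- spectral containers ------------------------------------------------

#' Normalised power spectrum of one displacement trace
#'
#' @slot frequency frequency grid, Hz (step `1/(nFft * fast-time step)`)
#' @slot power normalised power (maximum 1 unless degenerate)
#' @slot observationTime observation time of the underlying trace, s
#' @slot degenerate flag: the trace was all-zero/flat, power is all zero
#' @aliases PowerSpectrum
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  slots = c(frequency = "numeric", power = "numeric",
            observationTime = "numeric", degenerate = "logical"))

setValidity("PowerSpectrum", function(object) {
  if (length(object@frequency) != length(object@power))
    return("frequency and power lengths differ")
  if (length(object@power) &&
      (min(object@power) < -1e-12 || max(object@power) > 1 + 1e-9))
    return("power must be normalised to [0, 1]")
  TRUE
})

#' Coagulation spectrogram: per-measurement power spectra over observation
#' time
#'
#' Columns (one per observation time) are individually normalised to unit
#' maximum, matching the display convention of coagulation spectrograms.
#'
#' @slot observationTimes observation-time grid, s
#' @slot frequency frequency grid, Hz
#' @slot power `length(frequency) x length(observationTimes)` matrix
#' @slot degenerate per-column flag (all-zero or missing input)
#' @aliases Spectrogram
#' @exportClass Spectrogram
setClass("Spectrogram",
  slots = c(observationTimes = "numeric", frequency = "numeric",
            power = "matrix", degenerate = "logical"))

setValidity("Spectrogram", function(object) {
  if (!all(dim(object@power) ==
           c(length(object@frequency), length(object@observationTimes))))
    return("power matrix dimensions inconsistent")
  if (length(object@degenerate) != length(object@observationTimes))
    return("degenerate must have one flag per observation time")
  TRUE
})

#' Resonant-frequency trace over observation time
#'
#' The spectral peak per measurement: peak frequency, -3 dB width and
#' normalised peak power. Degenerate or missing measurements are `NA`.
#'
#' @slot observationTimes observation-time grid, s
#' @slot peakFrequency resonant frequency per observation time, Hz
#' @slot peakWidth -3 dB width of the spectral peak, Hz
#' @slot peakPower normalised peak power
#' @aliases FrequencyTrace
#' @exportClass FrequencyTrace
setClass("FrequencyTrace",
  slots = c(observationTimes = "numeric", peakFrequency = "numeric",
            peakWidth = "numeric", peakPower = "numeric"))

setValidity("FrequencyTrace", function(object) {
  n <- length(object@observationTimes)
  if (length(object@peakFrequency) != n || length(object@peakWidth) != n ||
      length(object@peakPower) != n)
    return("all slots must share the observation-time length")
  w <- object@peakWidth[is.finite(object@peakWidth)]
  if (length(w) && min(w) < 0) return("peakWidth must be >= 0")
  TRUE
})

# ---- coagulation parameters --------------------------------------------

#' Coagulation parameters extracted from a resonant-frequency trace
#'
#' `fInt` is the mean resonant frequency over the first minute, `fEnd` over
#' the last five minutes; `tInt` is the clotting start time (first sustained
#' 5 % rise above `fInt`), `tEnd` the clotting end time (first sustained
#' crossing of 95 % of `fEnd`), and `duration = tEnd - tInt`. Flags:
#' `no_clot` (no sustained rise), `truncated` (trace shorter than the
#' averaging windows), `low_confidence`.
#'
#' @slot channel channel index (NA if unknown)
#' @slot fInt,fEnd initial/final resonant frequency, Hz
#' @slot tInt,tEnd clotting start/end times, s (NA when `no_clot`)
#' @slot duration clotting duration `tEnd - tInt`, s
#' @slot flags character vector, subset of
#'   `c("no_clot", "truncated", "low_confidence")`
#' @aliases CoagulationParams
#' @exportClass CoagulationParams
setClass("CoagulationParams",
  slots = c(channel = "integer", fInt = "numeric", fEnd = "numeric",
            tInt = "numeric", tEnd = "numeric", duration = "numeric",
            flags = "character"))

setValidity("CoagulationParams", function(object) {
  if (!all(object@flags %in% c("no_clot", "truncated", "low_confidence")))
    return("unknown flag")
  if (!"no_clot" %in% object@flags &&
      is.finite(object@tInt) && is.finite(object@tEnd)) {
    if (object@tInt > object@tEnd) return("tInt must be <= tEnd")
    if (abs(object@duration - (object@tEnd - object@tInt)) > 1e-9)
      return("duration must equal tEnd - tInt")
  }
  TRUE
})
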