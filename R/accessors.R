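#' @rdname WellGeometry-class
setMethod("wavenumber", "WellGeometry",
          function(object) object@modeConstant / object@radius)

#' @rdname AcquisitionConfig-class
setMethod("fastTimeStep", "AcquisitionConfig",
          function(object) 1 / object@prf)

#' @rdname AcquisitionConfig-class
setMethod("pushDuration", "AcquisitionConfig",
          function(object) object@pushCycles / object@centerFrequency)

#' @rdname RarRun-class
setMethod("observationTimes", "RarRun",
          function(object) object@observationTimes)

#' @rdname DisplacementMatrix-class
setMethod("observationTimes", "DisplacementMatrix",
          function(object) object@observationTimes)

#' @rdname Spectrogram-class
setMethod("observationTimes", "Spectrogram",
          function(object) object@observationTimes)

#' @rdname FrequencyTrace-class
setMethod("observationTimes", "FrequencyTrace",
          function(object) object@observationTimes)

#' @rdname RarMeasurement-class
setMethod("alines", "RarMeasurement", function(object) object@alines)

#' @rdname RarMeasurement-class
setMethod("pulseRole", "RarMeasurement", function(object) object@pulseRole)

#' @rdname DisplacementTrace-class
setMethod("fastTime", "DisplacementTrace", function(object) object@tau)

#' @rdname DisplacementMatrix-class
setMethod("fastTime", "DisplacementMatrix", function(object) object@tau)

#' @rdname DisplacementTrace-class
setMethod("displacement", "DisplacementTrace",
          function(object) object@displacement)

#' @rdname DisplacementMatrix-class
setMethod("displacement", "DisplacementMatrix",
          function(object) object@displacement)

#' @rdname DisplacementTrace-class
setMethod("correlationPeak", "DisplacementTrace",
          function(object) object@correlationPeak)

#' @rdname FrequencyTrace-class
setMethod("peakFrequencies", "FrequencyTrace",
          function(object) object@peakFrequency)

#' @rdname FrequencyTrace-class
setMethod("peakWidths", "FrequencyTrace", function(object) object@peakWidth)

#' @describeIn CoagulationParams-class one-row data.frame of the parameters
#'   (frequencies in Hz, times in s, flags collapsed with `;`)
#' @param x a `CoagulationParams` object
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
as.data.frame.CoagulationParams <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(channel = x@channel, f_int_Hz = x@fInt, f_end_Hz = x@fEnd,
             T_int_s = x@tInt, T_end_s = x@tEnd, duration_s = x@duration,
             flags = paste(x@flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

# ---- show methods -------------------------------------------------------

setMethod("show", "WellGeometry", function(object) {
  cat("WellGeometry: radius", format(object@radius * 1e3), "mm,",
      "mode constant", format(object@modeConstant),
      "-> k =", format(wavenumber(object)), "1/m\n")
})

setMethod("show", "AcquisitionConfig", function(object) {
  cat("AcquisitionConfig\n")
  cat("  ", object@nChannels, "channel(s),",
      format(object@centerFrequency / 1e6), "MHz centre,",
      format(object@samplingRate / 1e6), "MHz sampling\n")
  cat("  ", object@nBaselinePulses, "baseline +",
      object@nDetectionPulses, "detection pulses at",
      format(object@prf / 1e3), "kHz PRF; push",
      format(pushDuration(object) * 1e6), "us\n")
  cat("   measurements every", format(object@measurementInterval),
      "s for", format(object@totalDuration), "s; SNR",
      format(object@noiseSnrDb), "dB; seed", object@seed, "\n")
})

setMethod("show", "CoagulationTrajectory", function(object) {
  cat("CoagulationTrajectory (", object@shape, ")\n", sep = "")
  cat("   f:", format(object@fLiquid), "->", format(object@fSolid),
      "Hz over [", format(object@tStart), ",", format(object@tEnd), "] s\n")
  cat("   amplitude:", format(object@ampLiquid * 1e6), "->",
      format(object@ampSolid * 1e6), "um; decay:",
      format(object@decayLiquid * 1e3), "->",
      format(object@decaySolid * 1e3), "ms\n")
})

setMethod("show", "RarMeasurement", function(object) {
  cat("RarMeasurement: channel", object@channel, "at T =",
      format(object@observationTime), "s;",
      nrow(object@alines), "A-lines x", ncol(object@alines), "samples\n")
})

setMethod("show", "RarRun", function(object) {
  cat("RarRun:", object@config@nChannels, "channel(s),",
      length(object@observationTimes), "measurements (T =",
      format(min(object@observationTimes)), "...",
      format(max(object@observationTimes)), "s)\n")
  if (length(object@truth)) cat("   ground truth attached\n")
})

setMethod("show", "DisplacementTrace", function(object) {
  cat("DisplacementTrace: channel", object@channel, "at T =",
      format(object@observationTime), "s;", length(object@tau),
      "samples; peak |S| =",
      format(max(abs(object@displacement), na.rm = TRUE) * 1e6), "um;",
      sum(object@lowConfidence), "low-confidence\n")
})

setMethod("show", "DisplacementMatrix", function(object) {
  cat("DisplacementMatrix: channel", object@channel, ";",
      length(object@observationTimes), "observation times x",
      length(object@tau), "fast-time samples;",
      sum(object@gap), "gap(s)\n")
})

setMethod("show", "PowerSpectrum", function(object) {
  if (object@degenerate) {
    cat("PowerSpectrum (degenerate) at T =",
        format(object@observationTime), "s\n")
  } else {
    cat("PowerSpectrum at T =", format(object@observationTime), "s;",
        length(object@frequency), "bins up to",
        format(max(object@frequency)), "Hz\n")
  }
})

setMethod("show", "Spectrogram", function(object) {
  cat("Spectrogram:", length(object@observationTimes),
      "observation times x", length(object@frequency), "frequency bins;",
      sum(object@degenerate), "degenerate column(s)\n")
})

setMethod("show", "FrequencyTrace", function(object) {
  f <- object@peakFrequency[is.finite(object@peakFrequency)]
  cat("FrequencyTrace:", length(object@observationTimes), "points")
  if (length(f)) cat("; f =", format(min(f)), "...", format(max(f)), "Hz")
  cat("\n")
})

setMethod("show", "CoagulationParams", function(object) {
  cat("CoagulationParams (channel", object@channel, ")\n")
  cat("   f_int =", format(object@fInt), "Hz, f_end =",
      format(object@fEnd), "Hz\n")
  cat("   T_int =", format(object@tInt), "s, T_end =",
      format(object@tEnd), "s, duration =", format(object@duration), "s\n")
  if (length(object@flags))
    cat("   flags:", paste(object@flags, collapse = ", "), "\n")
})
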