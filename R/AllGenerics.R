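# Generics for the accessor surface. Accessors rather than @ access are the
# supported interface; slot layout may change between versions.

#' @rdname WellGeometry-class
#' @param object,x an object of the documented class
#' @export
setGeneric("wavenumber", function(object) standardGeneric("wavenumber"))

#' @rdname AcquisitionConfig-class
#' @export
setGeneric("fastTimeStep", function(object) standardGeneric("fastTimeStep"))

#' @rdname AcquisitionConfig-class
#' @export
setGeneric("pushDuration", function(object) standardGeneric("pushDuration"))

#' @rdname RarRun-class
#' @export
setGeneric("observationTimes",
           function(object) standardGeneric("observationTimes"))

#' @rdname RarMeasurement-class
#' @export
setGeneric("alines", function(object) standardGeneric("alines"))

#' @rdname RarMeasurement-class
#' @export
setGeneric("pulseRole", function(object) standardGeneric("pulseRole"))

#' @rdname DisplacementTrace-class
#' @export
setGeneric("fastTime", function(object) standardGeneric("fastTime"))

#' @rdname DisplacementTrace-class
#' @export
setGeneric("displacement", function(object) standardGeneric("displacement"))

#' @rdname DisplacementTrace-class
#' @export
setGeneric("correlationPeak",
           function(object) standardGeneric("correlationPeak"))

#' @rdname FrequencyTrace-class
#' @export
setGeneric("peakFrequencies",
           function(object) standardGeneric("peakFrequencies"))

#' @rdname FrequencyTrace-class
#' @export
setGeneric("peakWidths", function(object) standardGeneric("peakWidths"))

#' Extract the spectral peak of a power spectrum
#'
#' Finds the global maximum of the normalised power spectrum inside a search
#' band, refines it by 3-point parabolic interpolation on log power, and
#' measures the -3 dB (half-power) width around the peak. At exactly tied
#' peak powers the lowest frequency wins.
#'
#' @param object a [PowerSpectrum-class] object
#' @param band numeric length-2 search band in Hz; the default spans 10 Hz
#'   (to reject residual DC leakage) to 80 % of the spectral Nyquist
#' @return a list with components `frequency` (Hz), `width` (-3 dB span,
#'   Hz; `NA` when the half-power crossing leaves the spectrum), and
#'   `power` (normalised peak power). All-`NA` for degenerate spectra.
#' @export
setGeneric("peakFrequency",
           function(object, band = NULL) standardGeneric("peakFrequency"))

#' Compute the normalised power spectrum of a displacement trace
#'
#' The trace is mean-subtracted, zero-padded to `nFft` points, transformed
#' with an FFT and the one-sided magnitude-squared spectrum normalised to
#' unit maximum. An all-zero (or constant) trace yields a flat zero spectrum
#' flagged degenerate rather than a division by zero.
#'
#' @param object a [DisplacementTrace-class] or a plain numeric vector
#' @param nFft FFT length; default: 4 x trace length rounded up to the next
#'   power of two (zero-padding stabilises the parabolic peak interpolation)
#' @param dt fast-time sampling step in seconds (required for numeric input;
#'   taken from the trace otherwise)
#' @param ... passed through between methods
#' @return a [PowerSpectrum-class] object
#' @export
setGeneric("powerSpectrum",
           function(object, nFft = NULL, ...) standardGeneric("powerSpectrum"))
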