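# Coagulation-parameter extraction from a resonant-frequency trace.
#
# f_int: mean resonant frequency over the first minute of measurements;
# f_end: mean over the last five minutes. T_int: first observation time at
# which the frequency has risen 5 % above f_int; T_end: first time it
# reaches 95 % of f_end. Clotting duration = T_end - T_int. Threshold
# crossings must persist for two consecutive samples so a single noise
# spike never triggers them; missing (NA) samples are skipped, never
# treated as crossings.

# 3-point median filter tolerating NAs (NA positions stay NA; neighbours
# are taken from the non-NA values around them)
.median3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  for (i in 2:(n - 1L)) {
    w <- x[(i - 1L):(i + 1L)]
    if (!is.na(x[i])) out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

.windowMean <- function(trace, lo, hi) {
  sel <- trace@observationTimes >= lo & trace@observationTimes <= hi
  f <- trace@peakFrequency[sel]
  mean(f[is.finite(f)])
}

#' Initial resonant frequency f_int
#'
#' Arithmetic mean of the resonant frequency over the first minute of
#' measurements, `[T0, T0 + 60 s]` with `T0` the first observation time.
#' Traces spanning less than 60 s are averaged over what is available and
#' flagged truncated by [extractParams()].
#'
#' @param trace a [FrequencyTrace-class]
#' @return f_int in Hz
#' @export
initialFrequency <- function(trace) {
  T0 <- trace@observationTimes[1]
  .windowMean(trace, T0, T0 + 60)
}

#' Final resonant frequency f_end
#'
#' Arithmetic mean of the resonant frequency over the last five minutes of
#' measurements, `[T_last - 300 s, T_last]`.
#'
#' @param trace a [FrequencyTrace-class]
#' @return f_end in Hz
#' @export
finalFrequency <- function(trace) {
  Tl <- trace@observationTimes[length(trace@observationTimes)]
  .windowMean(trace, Tl - 300, Tl)
}

# first observation time whose frequency reaches `threshold` and whose next
# non-NA sample (if any) confirms it
.firstSustainedCrossing <- function(times, f, threshold) {
  ok <- which(is.finite(f) & f >= threshold)
  for (i in ok) {
    later <- which(is.finite(f) & seq_along(f) > i)
    if (!length(later) || f[later[1]] >= threshold) return(times[i])
  }
  NA_real_
}

#' Clotting start time T_int
#'
#' The first observation time at which the resonant frequency has increased
#' by 5 % above `fInt`, sustained for two consecutive valid samples.
#' Returns `NA` when the rise never happens (no clot).
#'
#' @param trace a [FrequencyTrace-class]
#' @param fInt initial frequency, Hz (see [initialFrequency()])
#' @param riseFactor relative rise defining clotting onset (default 1.05)
#' @return T_int in s, or `NA`
#' @export
clottingStart <- function(trace, fInt, riseFactor = 1.05) {
  if (!is.finite(fInt) || fInt <= 0) stop("'fInt' must be positive")
  .firstSustainedCrossing(trace@observationTimes, trace@peakFrequency,
                          riseFactor * fInt)
}

#' Clotting end time T_end
#'
#' The first observation time at which the resonant frequency reaches 95 %
#' of `fEnd`, sustained for two consecutive valid samples.
#'
#' @param trace a [FrequencyTrace-class]
#' @param fEnd final frequency, Hz (see [finalFrequency()])
#' @param endFraction fraction of `fEnd` defining clotting completion
#'   (default 0.95)
#' @return T_end in s, or `NA`
#' @export
clottingEnd <- function(trace, fEnd, endFraction = 0.95) {
  if (!is.finite(fEnd) || fEnd <= 0) stop("'fEnd' must be positive")
  .firstSustainedCrossing(trace@observationTimes, trace@peakFrequency,
                          endFraction * fEnd)
}

#' Extract coagulation parameters from a resonant-frequency trace
#'
#' Composes [initialFrequency()], [finalFrequency()], [clottingStart()] and
#' [clottingEnd()] into a [CoagulationParams-class] record. A 3-point
#' median filter (default on) suppresses single-sample outliers before
#' thresholding. Samples with `fEnd < riseFactor * fInt` show no meaningful
#' rise and are flagged `no_clot` rather than reported with a degenerate
#' near-zero duration; traces shorter than the averaging windows are
#' flagged `truncated` and evaluated best-effort. If more than half of the
#' underlying spectral peaks were degenerate or missing the record is
#' flagged `low_confidence`. Never raises on a no-clot trace.
#'
#' @param trace a [FrequencyTrace-class]
#' @param channel channel index stored in the result
#' @param medianFilter apply the 3-point median pre-filter
#' @param riseFactor,endFraction threshold conventions (see
#'   [clottingStart()], [clottingEnd()])
#' @return a [CoagulationParams-class]
#' @export
extractParams <- function(trace, channel = NA_integer_,
                          medianFilter = TRUE,
                          riseFactor = 1.05, endFraction = 0.95) {
  flags <- character()
  Tm <- trace@observationTimes
  span <- if (length(Tm)) max(Tm) - min(Tm) else 0
  if (span < 300) flags <- c(flags, "truncated")
  if (mean(!is.finite(trace@peakFrequency)) > 0.5)
    flags <- c(flags, "low_confidence")
  work <- trace
  if (medianFilter) work@peakFrequency <- .median3(trace@peakFrequency)
  fInt <- initialFrequency(work)
  fEnd <- finalFrequency(work)
  tInt <- tEnd <- dur <- NA_real_
  if (!is.finite(fInt) || !is.finite(fEnd) || fEnd < riseFactor * fInt) {
    flags <- c(flags, "no_clot")
  } else {
    tInt <- clottingStart(work, fInt, riseFactor)
    tEnd <- clottingEnd(work, fEnd, endFraction)
    if (is.na(tInt) || is.na(tEnd)) {
      flags <- c(flags, "no_clot")
      tInt <- tEnd <- NA_real_
    } else {
      # a barely-rising trace can cross 95% of f_end before the 5% rise;
      # clamp so T_int <= T_end always holds for clotting samples
      tEnd <- max(tEnd, tInt)
      dur <- tEnd - tInt
    }
  }
  new("CoagulationParams", channel = as.integer(channel), fInt = fInt,
      fEnd = fEnd, tInt = tInt, tEnd = tEnd, duration = dur,
      flags = unique(flags))
}
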