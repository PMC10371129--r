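# Spectral analysis of displacement traces.
#
# Traces are analysed with a plain (rectangular-window) FFT: the ring-down
# decays naturally within the fast-time window, so additional tapering
# mostly broadens the peak. Zero-padding to ~4x the trace length refines
# the grid enough for stable 3-point parabolic peak interpolation.

.nextPow2 <- function(n) 2^ceiling(log2(n))

.powerSpectrumCore <- function(x, dt, nFft, observationTime) {
  n <- length(x)
  if (is.null(nFft)) nFft <- .nextPow2(4L * n)
  if (nFft < n) stop("nFft must be >= trace length", call. = FALSE)
  half <- floor(nFft / 2) + 1L
  freq <- (seq_len(half) - 1) / (nFft * dt)
  if (anyNA(x) || !all(is.finite(x)) || stats::sd(x) == 0) {
    return(new("PowerSpectrum", frequency = freq, power = rep(0, half),
               observationTime = observationTime, degenerate = TRUE))
  }
  x <- x - mean(x)
  X <- stats::fft(c(x, rep(0, nFft - n)))
  p <- Mod(X[seq_len(half)])^2
  pm <- max(p)
  if (pm <= 0) {
    return(new("PowerSpectrum", frequency = freq, power = rep(0, half),
               observationTime = observationTime, degenerate = TRUE))
  }
  new("PowerSpectrum", frequency = freq, power = p / pm,
      observationTime = observationTime, degenerate = FALSE)
}

#' @rdname powerSpectrum
setMethod("powerSpectrum", "DisplacementTrace",
  function(object, nFft = NULL, ...) {
    if (length(object@tau) < 8L)
      stop("trace must have at least 8 samples", call. = FALSE)
    dt <- object@tau[2] - object@tau[1]
    .powerSpectrumCore(object@displacement, dt, nFft,
                       object@observationTime)
  })

#' @rdname powerSpectrum
setMethod("powerSpectrum", "numeric",
  function(object, nFft = NULL, dt, ...) {
    if (length(object) < 8L)
      stop("trace must have at least 8 samples", call. = FALSE)
    .powerSpectrumCore(object, dt, nFft, NA_real_)
  })

#' @rdname peakFrequency
setMethod("peakFrequency", "PowerSpectrum", function(object, band = NULL) {
  if (object@degenerate)
    return(list(frequency = NA_real_, width = NA_real_, power = NA_real_))
  freq <- object@frequency
  p <- object@power
  if (is.null(band)) band <- c(10, 0.8 * max(freq))
  inBand <- freq >= band[1] & freq <= band[2]
  if (!any(inBand))
    return(list(frequency = NA_real_, width = NA_real_, power = NA_real_))
  pb <- ifelse(inBand, p, -Inf)
  i <- which.max(pb)            # ties: lowest frequency (first index)
  df <- freq[2] - freq[1]
  fpk <- freq[i]
  if (i > 1L && i < length(p) && p[i - 1] > 0 && p[i + 1] > 0) {
    y1 <- log(p[i - 1]); y2 <- log(p[i]); y3 <- log(p[i + 1])
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) fpk <- fpk + 0.5 * (y1 - y3) / denom * df
  }
  # -3 dB (half-power) span around the peak, linearly interpolated
  half <- p[i] / 2
  lo <- NA_real_; hi <- NA_real_
  j <- i
  while (j > 1L && p[j - 1] >= half) j <- j - 1L
  if (j > 1L) {
    lo <- freq[j - 1] + df * (half - p[j - 1]) / (p[j] - p[j - 1])
  }
  j <- i
  while (j < length(p) && p[j + 1] >= half) j <- j + 1L
  if (j < length(p)) {
    hi <- freq[j] + df * (p[j] - half) / (p[j] - p[j + 1])
  }
  width <- if (is.na(lo) || is.na(hi)) NA_real_ else hi - lo
  list(frequency = fpk, width = width, power = p[i])
})

#' Build the coagulation spectrogram and resonant-frequency trace
#'
#' Applies [powerSpectrum()] and [peakFrequency()] to every observation
#' time of a displacement matrix. Spectrogram columns are individually
#' normalised to unit maximum; gap or degenerate measurements propagate as
#' flagged all-zero columns and `NA` trace points.
#'
#' @param matrix a [DisplacementMatrix-class]
#' @param nFft FFT length (default 4 x the fast-time length, next power of
#'   two)
#' @param band peak search band in Hz, see [peakFrequency()]
#' @return a list with components `spectrogram` ([Spectrogram-class]) and
#'   `trace` ([FrequencyTrace-class])
#' @export
buildSpectrogram <- function(matrix, nFft = NULL, band = NULL) {
  Tm <- matrix@observationTimes
  nT <- length(Tm)
  ntau <- length(matrix@tau)
  if (nT == 0L || ntau == 0L) {
    sg <- new("Spectrogram", observationTimes = numeric(0),
              frequency = numeric(0),
              power = base::matrix(numeric(0), 0, 0),
              degenerate = logical(0))
    ft <- new("FrequencyTrace", observationTimes = numeric(0),
              peakFrequency = numeric(0), peakWidth = numeric(0),
              peakPower = numeric(0))
    return(list(spectrogram = sg, trace = ft))
  }
  dt <- matrix@tau[2] - matrix@tau[1]
  if (is.null(nFft)) nFft <- .nextPow2(4L * ntau)
  half <- floor(nFft / 2) + 1L
  P <- base::matrix(0, half, nT)
  degen <- logical(nT)
  fpk <- wid <- ppk <- rep(NA_real_, nT)
  freq <- (seq_len(half) - 1) / (nFft * dt)
  for (m in seq_len(nT)) {
    row <- matrix@displacement[m, ]
    if (matrix@gap[m] || anyNA(row)) {
      degen[m] <- TRUE
      next
    }
    ps <- .powerSpectrumCore(row, dt, nFft, Tm[m])
    P[, m] <- ps@power
    degen[m] <- ps@degenerate
    if (!ps@degenerate) {
      pk <- peakFrequency(ps, band = band)
      fpk[m] <- pk$frequency
      wid[m] <- pk$width
      ppk[m] <- pk$power
    }
  }
  sg <- new("Spectrogram", observationTimes = Tm, frequency = freq,
            power = P, degenerate = degen)
  ft <- new("FrequencyTrace", observationTimes = Tm, peakFrequency = fpk,
            peakWidth = wid, peakPower = ppk)
  list(spectrogram = sg, trace = ft)
}
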