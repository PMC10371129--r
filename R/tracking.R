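# Echo tracking: A-line matrix -> surface-displacement trace.
#
# Each detection echo is compared to the *equilibrium* reference (the mean
# of the baseline A-lines, which suppresses per-pulse amplitude jitter),
# never to the previous echo, so no motion accumulation or drift occurs.
# The time shift maximising the normalised cross-correlation inside a gate
# around the surface echo, refined to sub-sample precision by 3-point
# parabolic interpolation of the correlation peak, converts to displacement
# as soundSpeed * delay / 2 (positive = away from the transducer).

#' @useDynLib rheowave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# envelope via moving RMS over one carrier period
.envelope <- function(x, samplesPerCycle) {
  k <- max(3L, as.integer(round(samplesPerCycle)))
  e <- stats::filter(x^2, rep(1 / k, k), sides = 2)
  e[is.na(e)] <- 0
  sqrt(as.numeric(e))
}

#' Build the equilibrium reference echo of a measurement
#'
#' Averages the baseline A-lines (acquired before the push) pointwise to a
#' single low-noise reference trace and locates the sample-surface echo as
#' the maximum of its envelope — the air-sample interface reflects almost
#' totally, so its echo dominates the deeper part of the record. The
#' reference is returned restricted to a gate of `gateFactor` pulse lengths
#' (-6 dB envelope durations) on each side of the echo centre.
#'
#' @param record a [RarMeasurement-class] with at least one baseline pulse
#' @param gateFactor gate half-width in units of the pulse length
#' @return a list: `reference` (gated mean baseline trace), `gate` (column
#'   indices of the gate in the A-line), `center` (echo-centre column),
#'   `full` (ungated mean baseline trace)
#' @export
buildReference <- function(record, gateFactor = 3) {
  bl <- record@pulseRole == "baseline"
  if (!any(bl)) stop("record contains no baseline pulses", call. = FALSE)
  config <- record@config
  full <- colMeans(record@alines[bl, , drop = FALSE])
  env <- .envelope(full, config@samplingRate / config@centerFrequency)
  center <- which.max(env)
  pulseLen <- 2 * sqrt(2 * log(2)) * .pulseSigmaT(config)  # -6 dB duration
  hw <- as.integer(round(gateFactor * pulseLen * config@samplingRate))
  gate <- (center - hw):(center + hw)
  if (gate[1] < 1L || gate[length(gate)] > length(full))
    stop("surface-echo gate exceeds the record window", call. = FALSE)
  list(reference = full[gate], gate = gate, center = center, full = full)
}

#' Estimate the arrival-time delay between a reference and an echo
#'
#' Scans every integer lag in `[-maxLag, maxLag]` for the normalised
#' cross-correlation maximum, then refines the peak location to sub-sample
#' precision with a 3-point parabolic fit. A positive delay means the echo
#' arrived later than the reference. If the correlation peak falls below
#' `corrFloor` the sample is flagged low-confidence (the value is
#' retained).
#'
#' @param reference gated reference trace (length L)
#' @param echo gated echo trace: either the same length (implicitly
#'   zero-padded at the gate edges) or length `L + 2*maxLag`
#' @param samplingRate digitiser sampling rate, Hz
#' @param searchWindow maximum delay magnitude searched, s
#' @param corrFloor low-confidence threshold on the correlation peak
#' @return a list: `delay` (s), `lagSamples` (fractional samples),
#'   `lagInteger` (the integer lag maximising the correlation), `peak`
#'   (normalised correlation at that maximum), `lowConfidence`
#' @export
#' @examples
#' cfg <- acquisitionConfig(noiseSnrDb = Inf, amplitudeJitter = 0)
#' ref <- synthesizeAline(cfg, 0)
#' estimateDelay(ref, ref, cfg@samplingRate)$delay  # 0
estimateDelay <- function(reference, echo, samplingRate,
                          searchWindow = 0.5e-6, corrFloor = 0.5) {
  maxLag <- as.integer(round(searchWindow * samplingRate))
  L <- length(reference)
  if (length(echo) == L) {
    echo <- c(rep(0, maxLag), echo, rep(0, maxLag))
  } else if (length(echo) != L + 2L * maxLag) {
    stop("echo must have length L or L + 2*maxLag", call. = FALSE)
  }
  cc <- .nccLags(matrix(echo, nrow = 1), reference, maxLag)[1, ]
  i <- which.max(cc)
  delta <- 0
  if (i > 1L && i < length(cc)) {
    y1 <- cc[i - 1L]; y2 <- cc[i]; y3 <- cc[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) delta <- 0.5 * (y1 - y3) / denom
  }
  lag <- (i - maxLag - 1L) + delta
  list(delay = lag / samplingRate, lagSamples = lag,
       lagInteger = i - maxLag - 1L, peak = cc[i],
       lowConfidence = cc[i] < corrFloor)
}

#' Convert an echo delay to a surface displacement
#'
#' At constant sound speed the round trip changes by twice the surface
#' motion, so `displacement = soundSpeed * delay / 2`, signed: a later echo
#' (positive delay) means the surface moved away from the transducer.
#'
#' @param delay echo arrival delay relative to equilibrium, s
#' @param soundSpeed speed of sound, m/s
#' @return displacement in metres; vectorised over `delay`
#' @export
#' @examples
#' delayToDisplacement(10e-9, 1480)  # 7.4 um
delayToDisplacement <- function(delay, soundSpeed) {
  if (soundSpeed <= 0) stop("'soundSpeed' must be positive", call. = FALSE)
  soundSpeed * delay / 2
}

#' Track the surface displacement through one RAR measurement
#'
#' Builds the equilibrium reference from the baseline pulses, then applies
#' [estimateDelay()] + [delayToDisplacement()] to every detection pulse in
#' fast-time order. The correlation is restricted to a gate around the
#' surface echo; the lag scan runs over `searchWindow` on both sides.
#'
#' @param record a [RarMeasurement-class]
#' @inheritParams estimateDelay
#' @param gateFactor gate half-width in pulse lengths (see
#'   [buildReference()])
#' @return a [DisplacementTrace-class]
#' @export
trackMeasurement <- function(record, searchWindow = 0.5e-6,
                             corrFloor = 0.5, gateFactor = 3) {
  config <- record@config
  fs <- config@samplingRate
  maxLag <- as.integer(round(searchWindow * fs))
  ref <- buildReference(record, gateFactor = gateFactor)
  gate <- ref$gate
  wide <- (gate[1] - maxLag):(gate[length(gate)] + maxLag)
  n <- ncol(record@alines)
  if (wide[1] < 1L || wide[length(wide)] > n)
    stop("search window exceeds the record; reduce searchWindow or ",
         "extend the record window", call. = FALSE)
  det <- record@pulseRole == "detection"
  E <- record@alines[det, wide, drop = FALSE]
  cc <- .nccLags(E, ref$reference, maxLag)

  i <- max.col(cc, ties.method = "first")
  P <- nrow(cc)
  nl <- ncol(cc)
  y2 <- cc[cbind(seq_len(P), i)]
  inner <- i > 1L & i < nl
  delta <- numeric(P)
  if (any(inner)) {
    ii <- which(inner)
    y1 <- cc[cbind(ii, i[ii] - 1L)]
    y3 <- cc[cbind(ii, i[ii] + 1L)]
    denom <- y1 - 2 * y2[ii] + y3
    ok <- denom < 0
    delta[ii[ok]] <- 0.5 * (y1[ok] - y3[ok]) / denom[ok]
  }
  lag <- (i - maxLag - 1L) + delta
  disp <- delayToDisplacement(lag / fs, config@soundSpeed)
  new("DisplacementTrace", channel = record@channel,
      observationTime = record@observationTime, tau = record@tau,
      displacement = disp, correlationPeak = pmin(pmax(y2, -1), 1),
      lowConfidence = y2 < corrFloor)
}

#' Assemble displacement traces into the two-time matrix S(T, tau)
#'
#' Stacks the traces of one channel into a [DisplacementMatrix-class], rows
#' ordered by observation time regardless of input order. If `times` is
#' supplied, observation times without a trace become all-`NA` gap rows —
#' gaps are recorded, never interpolated.
#'
#' @param traces list of [DisplacementTrace-class] from a single channel
#'   sharing one fast-time grid
#' @param times optional full observation-time grid, s
#' @return a [DisplacementMatrix-class]
#' @export
assembleMatrix <- function(traces, times = NULL) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  ch <- unique(vapply(traces, function(x) x@channel, integer(1)))
  if (length(ch) != 1L)
    stop("traces from mixed channels: ", paste(ch, collapse = ", "),
         call. = FALSE)
  tau <- traces[[1]]@tau
  for (tr in traces)
    if (length(tr@tau) != length(tau) || any(tr@tau != tau))
      stop("traces do not share a fast-time grid", call. = FALSE)
  Tobs <- vapply(traces, function(x) x@observationTime, numeric(1))
  if (anyDuplicated(Tobs))
    stop("duplicated observation times", call. = FALSE)
  if (is.null(times)) times <- sort(Tobs)
  idx <- match(round(times, 9), round(Tobs, 9))
  nT <- length(times)
  S <- matrix(NA_real_, nT, length(tau))
  CP <- matrix(NA_real_, nT, length(tau))
  gap <- is.na(idx)
  for (r in which(!gap)) {
    S[r, ] <- traces[[idx[r]]]@displacement
    CP[r, ] <- traces[[idx[r]]]@correlationPeak
  }
  new("DisplacementMatrix", channel = ch, observationTimes = times,
      tau = tau, displacement = S, correlationPeak = CP, gap = gap)
}
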