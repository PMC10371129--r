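#' Band-limited circular shift of a sampled signal
#'
#' Shifts a real signal by a (possibly fractional) number of samples via an
#' FFT phase ramp — the ideal band-limited interpolator for periodic
#' signals. Used to construct echoes with exactly known sub-sample delays,
#' e.g. when validating delay estimators.
#'
#' @param x numeric vector
#' @param shift shift in samples; positive moves features to later indices
#' @return the shifted signal (same length, real)
#' @export
#' @examples
#' x <- sin(2 * pi * (0:63) / 16)
#' y <- fractionalShift(x, 2.5)
fractionalShift <- function(x, shift) {
  n <- length(x)
  k <- c(0:floor(n / 2), seq_len(ceiling(n / 2) - 1) - ceiling(n / 2))
  ph <- exp(-2i * pi * k * shift / n)
  if (n %% 2 == 0)  # keep the Nyquist bin real so the output stays real
    ph[n / 2 + 1] <- cos(2 * pi * (n / 2) * shift / n)
  Re(stats::fft(stats::fft(x) * ph, inverse = TRUE) / n)
}
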