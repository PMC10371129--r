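# End-to-end orchestration: track -> spectrogram -> parameters for every
# channel of a run, plus tabular/figure export.

#' Results of the full RAR analysis pipeline
#'
#' @slot config the [AcquisitionConfig-class] of the analysed run
#' @slot matrices per-channel [DisplacementMatrix-class]
#' @slot spectrograms per-channel [Spectrogram-class]
#' @slot traces per-channel [FrequencyTrace-class]
#' @slot params data.frame, one row of coagulation parameters per channel
#' @slot log per-stage counts of flagged samples
#' @aliases RarResults
#' @exportClass RarResults
setClass("RarResults",
  slots = c(config = "AcquisitionConfig", matrices = "list",
            spectrograms = "list", traces = "list", params = "data.frame",
            log = "data.frame"))

setMethod("show", "RarResults", function(object) {
  cat("RarResults:", length(object@matrices), "channel(s)\n")
  print(object@params, row.names = FALSE)
})

#' Run the full RAR analysis pipeline on a run
#'
#' Executes echo tracking, spectral analysis and coagulation-parameter
#' extraction for every channel of a (simulated or imported) run. A
#' measurement whose tracking fails is logged and becomes a gap row; the
#' remaining measurements are still processed (partial results with
#' flags, never a hard stop mid-run).
#'
#' @param run a [RarRun-class]
#' @param nFft FFT length for the spectrogram (default 4 x trace length)
#' @param band spectral peak search band, Hz (see [peakFrequency()])
#' @param medianFilter 3-point median pre-filter before thresholding
#' @param searchWindow,corrFloor,gateFactor tracking options (see
#'   [trackMeasurement()])
#' @param riseFactor,endFraction clotting-threshold conventions (see
#'   [extractParams()])
#' @return a [RarResults-class]
#' @export
#' @examples
#' cfg <- acquisitionConfig(totalDuration = 36, nChannels = 1L,
#'                          nDetectionPulses = 128L, nBaselinePulses = 4L,
#'                          samplingRate = 20e6)
#' run <- simulateRun(cfg, coagulationTrajectory(tStart = 6, tEnd = 18))
#' res <- runPipeline(run)
#' res@params
runPipeline <- function(run, nFft = NULL, band = NULL, medianFilter = TRUE,
                        searchWindow = 0.5e-6, corrFloor = 0.5,
                        gateFactor = 3, riseFactor = 1.05,
                        endFraction = 0.95) {
  nch <- run@config@nChannels
  matrices <- spectrograms <- traces <- vector("list", nch)
  params <- vector("list", nch)
  logRows <- vector("list", nch)
  for (ch in seq_len(nch)) {
    trs <- list()
    nFailed <- 0L
    for (rec in run@records[[ch]]) {
      tr <- tryCatch(
        trackMeasurement(rec, searchWindow = searchWindow,
                         corrFloor = corrFloor, gateFactor = gateFactor),
        error = function(e) {
          warning("channel ", ch, ", T = ", rec@observationTime,
                  " s: tracking failed (", conditionMessage(e),
                  "); recorded as gap", call. = FALSE)
          NULL
        })
      if (is.null(tr)) nFailed <- nFailed + 1L else trs[[length(trs) + 1L]] <- tr
    }
    if (!length(trs))
      stop("channel ", ch, ": no measurement could be tracked",
           call. = FALSE)
    dm <- assembleMatrix(trs, times = run@observationTimes)
    sp <- buildSpectrogram(dm, nFft = nFft, band = band)
    cp <- extractParams(sp$trace, channel = ch, medianFilter = medianFilter,
                        riseFactor = riseFactor, endFraction = endFraction)
    matrices[[ch]] <- dm
    spectrograms[[ch]] <- sp$spectrogram
    traces[[ch]] <- sp$trace
    params[[ch]] <- as.data.frame(cp)
    logRows[[ch]] <- data.frame(
      channel = ch,
      n_measurements = length(run@observationTimes),
      n_failed = nFailed,
      n_low_confidence = sum(vapply(trs, function(x) sum(x@lowConfidence),
                                    numeric(1))),
      n_degenerate_spectra = sum(sp$spectrogram@degenerate))
  }
  new("RarResults", config = run@config, matrices = matrices,
      spectrograms = spectrograms, traces = traces,
      params = do.call(rbind, params), log = do.call(rbind, logRows))
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(nm) <- NULL
  stats::setNames(out, nm)
}

#' Write pipeline results to CSV tables and a JSON manifest
#'
#' Writes `displacement.csv` (long format: channel, T, tau,
#' displacement_um, corr_peak, gap), `frequency_trace.csv` (channel, T,
#' f_peak_Hz, width_Hz, peak_power), `params.csv` (one row per channel) and
#' `manifest.json` recording the full configuration, every analysis
#' threshold used, the seed and the package version. Re-running on the same
#' inputs overwrites with identical content.
#'
#' @param results a [RarResults-class]
#' @param dir output directory (created if needed)
#' @param thresholds named list of analysis options to record in the
#'   manifest
#' @return `dir`, invisibly
#' @export
writeResults <- function(results, dir, thresholds = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(results@matrices, function(dm) {
    nT <- length(dm@observationTimes)
    data.frame(
      channel = dm@channel,
      T = rep(dm@observationTimes, each = length(dm@tau)),
      tau = rep(dm@tau, times = nT),
      displacement_um = as.vector(t(dm@displacement)) * 1e6,
      corr_peak = as.vector(t(dm@correlationPeak)),
      gap = rep(dm@gap, each = length(dm@tau)))
  }))
  utils::write.csv(long, file.path(dir, "displacement.csv"),
                   row.names = FALSE)
  ft <- do.call(rbind, lapply(seq_along(results@traces), function(ch) {
    tr <- results@traces[[ch]]
    data.frame(channel = ch, T = tr@observationTimes,
               f_peak_Hz = tr@peakFrequency, width_Hz = tr@peakWidth,
               peak_power = tr@peakPower)
  }))
  utils::write.csv(ft, file.path(dir, "frequency_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(results@params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "rheowave",
    version = as.character(utils::packageVersion("rheowave")),
    schema = 1L,
    config = .configAsList(results@config),
    thresholds = thresholds,
    log = results@log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Render heatmap and spectrogram figures per channel
#'
#' For each channel writes a PNG with (top) the surface-displacement
#' heatmap — fast time vs observation time, displacement colour-coded —
#' and (bottom) the spectrogram — frequency vs observation time,
#' normalised power — annotated with the recovered clotting start/end
#' times. Channels flagged `no_clot` get no markers; an empty channel
#' yields a placeholder panel with a note. Regeneration is deterministic
#' for fixed inputs.
#'
#' @param results a [RarResults-class]
#' @param dir output directory
#' @param fMax upper frequency limit of the spectrogram panel, Hz
#' @return character vector of figure paths, invisibly
#' @export
renderFigures <- function(results, dir, fMax = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in seq_along(results@matrices)) {
    dm <- results@matrices[[ch]]
    sg <- results@spectrograms[[ch]]
    p <- results@params[results@params$channel == ch, , drop = FALSE]
    path <- file.path(dir, sprintf("channel%02d.png", ch))
    grDevices::png(path, width = 900, height = 700)
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    if (all(dm@gap)) {
      graphics::plot.new()
      graphics::title(main = sprintf("channel %d: no data", ch))
      graphics::plot.new()
    } else {
      disp <- dm@displacement * 1e6
      disp[is.na(disp)] <- 0
      graphics::image(dm@observationTimes, dm@tau * 1e3, disp,
                      col = grDevices::hcl.colors(64, "Blue-Red 2"),
                      xlab = "observation time T (s)",
                      ylab = "fast time (ms)",
                      main = sprintf("channel %d: surface displacement (um)",
                                     ch))
      if (is.null(fMax)) fMax <- 0.25 * max(sg@frequency)
      sel <- sg@frequency <= fMax
      graphics::image(sg@observationTimes, sg@frequency[sel],
                      t(sg@power[sel, , drop = FALSE]),
                      col = grDevices::hcl.colors(64, "Inferno"),
                      xlab = "observation time T (s)", ylab = "frequency (Hz)",
                      main = "spectrogram (normalised power)")
      if (nrow(p) && !grepl("no_clot", p$flags)) {
        graphics::abline(v = c(p$T_int_s, p$T_end_s), col = "white",
                         lty = 2, lwd = 2)
        graphics::mtext(sprintf("T_int = %.0f s, T_end = %.0f s",
                                p$T_int_s, p$T_end_s), side = 3, line = -1.5,
                        col = "white")
      }
    }
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
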