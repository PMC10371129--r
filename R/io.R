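# Plain-text archive of a multichannel run: one directory per run holding
# the full acquisition configuration and observation grid as JSON
# (schema-versioned), per-channel A-line matrices as CSV (rows = pulses of
# all measurements stacked, tagged with observation time, role and fast
# time), and — for simulated runs — a ground-truth sidecar (CSV curve table
# plus JSON parameter truth).

.ARCHIVE_SCHEMA <- 1L

#' Write / read a RAR run archive
#'
#' `writeRarArchive()` serialises a run to a directory of plain-text files:
#' `config.json` (acquisition configuration, observation grid, schema
#' version), `channelNN.csv` (stacked A-line matrices with per-row
#' observation time, pulse role and fast time), and for simulated runs
#' `truth.csv` (channel, T, f_true, A_true) plus `truth_params.json`.
#' `readRarArchive()` reconstructs the identical [RarRun-class] (ground
#' truth curves and parameters included).
#'
#' @param run a [RarRun-class]
#' @param dir archive directory
#' @return `writeRarArchive`: `dir` invisibly; `readRarArchive`: a
#'   [RarRun-class]
#' @export
writeRarArchive <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- .configAsList(run@config)
  meta <- list(schema = .ARCHIVE_SCHEMA, config = cfg,
               observationTimes = run@observationTimes)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ch in seq_along(run@records)) {
    rows <- lapply(run@records[[ch]], function(rec) {
      nd <- length(rec@tau)
      nb <- nrow(rec@alines) - nd
      data.frame(T = rec@observationTime, role = rec@pulseRole,
                 tau = c(rep(NA_real_, nb), rec@tau),
                 rec@alines, check.names = FALSE)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, sprintf("channel%02d.csv", ch)),
                     row.names = FALSE)
  }
  if (length(run@truth)) {
    curves <- do.call(rbind, lapply(seq_along(run@truth), function(ch) {
      tr <- run@truth[[ch]]
      data.frame(channel = ch, T = run@observationTimes, f_true = tr$fTrue,
                 A_true = tr$ampTrue)
    }))
    utils::write.csv(curves, file.path(dir, "truth.csv"), row.names = FALSE)
    pars <- lapply(run@truth, function(tr) {
      p <- tr$params
      traj <- tr$trajectory
      list(f_int = p@fInt, f_end = p@fEnd, T_int = p@tInt, T_end = p@tEnd,
           duration = p@duration, flags = p@flags,
           trajectory = list(
             fLiquid = traj@fLiquid, fSolid = traj@fSolid,
             tStart = traj@tStart, tEnd = traj@tEnd, shape = traj@shape,
             ampLiquid = traj@ampLiquid, ampSolid = traj@ampSolid,
             decayLiquid = traj@decayLiquid, decaySolid = traj@decaySolid))
    })
    jsonlite::write_json(pars, file.path(dir, "truth_params.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname writeRarArchive
#' @export
readRarArchive <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$schema) || meta$schema != .ARCHIVE_SCHEMA)
    stop("unsupported archive schema: ", meta$schema, call. = FALSE)
  cl <- meta$config
  config <- new("AcquisitionConfig",
    centerFrequency = cl$centerFrequency, samplingRate = cl$samplingRate,
    prf = cl$prf, nBaselinePulses = as.integer(cl$nBaselinePulses),
    nDetectionPulses = as.integer(cl$nDetectionPulses),
    pushCycles = as.integer(cl$pushCycles),
    measurementInterval = cl$measurementInterval,
    totalDuration = cl$totalDuration, nChannels = as.integer(cl$nChannels),
    soundSpeed = cl$soundSpeed, surfaceDepth = cl$surfaceDepth,
    plateDepths = cl$plateDepths, plateAmplitudes = cl$plateAmplitudes,
    recordStart = cl$recordStart, recordDuration = cl$recordDuration,
    fractionalBandwidth = cl$fractionalBandwidth,
    noiseSnrDb = if (is.character(cl$noiseSnrDb)) Inf else cl$noiseSnrDb,
    amplitudeJitter = cl$amplitudeJitter, seed = as.integer(cl$seed))
  Tm <- meta$observationTimes
  records <- vector("list", config@nChannels)
  for (ch in seq_len(config@nChannels)) {
    df <- utils::read.csv(file.path(dir, sprintf("channel%02d.csv", ch)),
                          check.names = FALSE)
    records[[ch]] <- lapply(Tm, function(T) {
      sub <- df[abs(df$T - T) < 1e-9, , drop = FALSE]
      if (!nrow(sub))
        stop("archive: channel ", ch, " is missing T = ", T, " s",
             call. = FALSE)
      al <- as.matrix(sub[, -(1:3), drop = FALSE])
      dimnames(al) <- NULL
      new("RarMeasurement", channel = as.integer(ch), observationTime = T,
          alines = al, pulseRole = sub$role,
          tau = sub$tau[sub$role == "detection"], config = config)
    })
  }
  truth <- list()
  tp <- file.path(dir, "truth_params.json")
  if (file.exists(tp)) {
    pars <- jsonlite::read_json(tp, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    curves <- utils::read.csv(file.path(dir, "truth.csv"))
    truth <- lapply(seq_along(pars), function(ch) {
      p <- pars[[ch]]
      tj <- p$trajectory
      traj <- new("CoagulationTrajectory",
        fLiquid = tj$fLiquid, fSolid = tj$fSolid,
        tStart = if (is.null(tj$tStart) || is.character(tj$tStart)) Inf
                 else tj$tStart,
        tEnd = if (is.null(tj$tEnd) || is.character(tj$tEnd)) Inf
               else tj$tEnd,
        shape = tj$shape, ampLiquid = tj$ampLiquid, ampSolid = tj$ampSolid,
        decayLiquid = tj$decayLiquid, decaySolid = tj$decaySolid)
      sub <- curves[curves$channel == ch, , drop = FALSE]
      asNum <- function(x) if (is.null(x) || length(x) == 0) NA_real_
                           else as.numeric(x)
      list(trajectory = traj, fTrue = sub$f_true, ampTrue = sub$A_true,
           params = new("CoagulationParams", channel = as.integer(ch),
                        fInt = asNum(p$f_int), fEnd = asNum(p$f_end),
                        tInt = asNum(p$T_int), tEnd = asNum(p$T_end),
                        duration = asNum(p$duration),
                        flags = as.character(unlist(p$flags))))
    })
  }
  new("RarRun", config = config, observationTimes = Tm, records = records,
      truth = truth)
}
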