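#' @include AllClasses.R io.R
NULL

## internal: deterministic per-stage seed fan-out from the global seed
.stageSeed <- function(seed, stageIndex) {
  as.integer((as.numeric(seed) * 7919 + 104729 * stageIndex) %% 2147483647)
}

.pipelineError <- function(message, code) {
  structure(class = c("vacuoscopeError", "error", "condition"),
            list(message = message, call = NULL, code = code))
}

#' Load (and validate) a pipeline configuration
#'
#' The configuration is a named list (or a YAML file holding one) with a
#' global `seed`, a `stages` character vector drawn from
#' `simulate`, `track`, `quantify`, `ph`, `size_control`, and optional
#' per-stage parameter blocks mirroring the corresponding function
#' arguments. Every stochastic stage derives its own seed
#' deterministically from the global seed, so a config + seed pair fully
#' reproduces a run.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list.
#' @export
loadPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(.pipelineError(paste0("config file not found: ", config),
                          "input"))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop(.pipelineError("config must be a list or YAML path", "schema"))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages))
    config$stages <- c("simulate", "track", "quantify", "ph",
                       "size_control")
  bad <- setdiff(config$stages,
                 c("simulate", "track", "quantify", "ph", "size_control"))
  if (length(bad))
    stop(.pipelineError(paste0("unknown stage(s): ",
                               paste(bad, collapse = ", ")), "schema"))
  config
}

## internal: build the profile/channels requested by the simulate block
.simStage <- function(cfg, seed) {
  medium <- if (is.null(cfg$medium)) "SDC" else cfg$medium
  args <- cfg[intersect(names(cfg),
                        c("phBase", "phPeak", "period", "pulseFwhm",
                          "budToPeak", "peakToSep", "driftRate", "mode",
                          "noiseSd", "pulseRate"))]
  profile <- do.call(oscillationProfile, c(list(medium = medium), args))
  channels <- if (identical(cfg$channels, "ratio")) ratioChannels()
              else defaultChannels()
  simulateCohort(
    nCells = if (is.null(cfg$nCells)) 50 else cfg$nCells,
    duration = if (is.null(cfg$duration)) 1000 else cfg$duration,
    dt = if (is.null(cfg$dt)) 2 else cfg$dt,
    seed = seed, profile = profile, channels = channels,
    amplitudeMultiplier = if (is.null(cfg$amplitudeMultiplier))
      amplitudeMultiplierPreset(medium) else cfg$amplitudeMultiplier)
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order (`simulate` or trace input ->
#' `track` -> `quantify` -> `ph` -> `size_control`), writes each stage's
#' tabular outputs as CSV into `outDir`, and returns (and writes) a JSON
#' run report with versions, per-stage seeds and record counts. All
#' outputs are byte-reproducible from config + seed.
#'
#' @param config config list or YAML path, see [loadPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return the run report, invisibly.
#' @export
runPipeline <- function(config, outDir = ".") {
  config <- loadPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "vacuoscope",
                 version = as.character(utils::packageVersion("vacuoscope")),
                 seed = config$seed, stages = list())
  tr <- NULL; cohort <- NULL
  for (si in seq_along(config$stages)) {
    stage <- config$stages[si]
    sseed <- .stageSeed(config$seed, si)
    counts <- list()
    if (stage == "simulate") {
      cohort <- .simStage(config$simulate, sseed)
      tr <- traces(cohort)
      writeTraces(tr, file.path(outDir, "traces.csv"),
                  file.path(outDir, "annotations.csv"))
      counts$n_cells <- length(tr)
    } else if (stage == "track") {
      scfg <- config$track
      if (!is.null(scfg$tiff)) {
        files <- scfg$tiff
        missing <- files[!file.exists(unlist(files))]
        if (length(missing))
          stop(.pipelineError(paste0("missing input: ",
                                     paste(missing, collapse = ", ")),
                              "input"))
        stacks <- lapply(files, readStackTIFF,
                         dt = if (is.null(scfg$dt)) 2 else scfg$dt)
        names(stacks) <- names(files)
      } else {
        if (is.null(cohort))
          stop(.pipelineError("track stage needs tiff inputs or a simulate stage",
                              "input"))
        scene <- do.call(sceneConfig, config$scene %||% list())
        stacks <- renderImageStack(cohort, scene, seed = sseed)$stacks
      }
      res <- do.call(trackStacks, c(
        list(stacks = stacks),
        scfg[intersect(names(scfg),
                       c("bgRadius", "register", "diameter", "threshold",
                         "initialRadius", "radius", "trackChannel"))]))
      utils::write.csv(res$tracks, file.path(outDir, "tracks.csv"),
                       row.names = FALSE)
      writeTraces(res$traces, file.path(outDir, "extracted_traces.csv"))
      tr <- res$traces
      counts$n_detections <- nrow(res$detections)
      counts$n_tracks <- length(unique(res$tracks$track_id))
      counts$n_traces <- length(res$traces)
    } else if (stage == "quantify") {
      if (is.null(tr))
        stop(.pipelineError("quantify stage needs traces", "input"))
      qcfg <- config$quantify
      channel <- if (is.null(qcfg$channel)) "vsep" else qcfg$channel
      comp <- quantifyCohort(tr, channel = channel,
                             minSpan = qcfg$minSpan %||% 500)
      utils::write.csv(comp, file.path(outDir, "components.csv"),
                       row.names = FALSE)
      utils::write.csv(cohortSummary(comp, group = qcfg$group %||% "cohort",
                                     seed = sseed),
                       file.path(outDir, "cohort_summary.csv"),
                       row.names = FALSE)
      counts$n_cells <- nrow(comp)
    } else if (stage == "ph") {
      if (is.null(tr))
        stop(.pipelineError("ph stage needs traces", "input"))
      pcfg <- config$ph
      cal <- if (!is.null(pcfg$calibration)) {
        if (!file.exists(pcfg$calibration))
          stop(.pipelineError(paste0("missing input: ", pcfg$calibration),
                              "input"))
        readCalibration(pcfg$calibration)
      } else simulateCalibrationSeries(seed = sseed)
      fit <- fitCalibration(cal)
      channel <- pcfg$channel %||% "ratio"
      allPeaks <- list(); allCycles <- list()
      for (t in tr) {
        ph <- ratioToPh(fit, channelValues(t, channel))
        pk <- detectPeaks(as.numeric(ph), traceTimes(t))
        allPeaks[[cellId(t)]] <- pk
        if (nrow(pk))
          allCycles[[cellId(t)]] <- cbind(cell_id = cellId(t),
            cycleMetrics(as.numeric(ph), pk, traceTimes(t)))
      }
      cycles <- do.call(rbind, allCycles)
      utils::write.csv(cycles, file.path(outDir, "cycles.csv"),
                       row.names = FALSE)
      ivs <- eventIntervals(tr, allPeaks[vapply(tr, cellId, character(1))])
      utils::write.csv(ivs$summary, file.path(outDir, "intervals.csv"),
                       row.names = FALSE)
      counts$n_cycles <- if (is.null(cycles)) 0L else nrow(cycles)
      counts$n_peaks <- sum(vapply(allPeaks, nrow, numeric(1)))
    } else if (stage == "size_control") {
      ccfg <- config$size_control
      recs <- if (!is.null(ccfg$file)) {
        if (!file.exists(ccfg$file))
          stop(.pipelineError(paste0("missing input: ", ccfg$file),
                              "input"))
        readSizeRecords(ccfg$file)
      } else do.call(simulateSizeCohort, c(
        list(seed = sseed),
        ccfg[intersect(names(ccfg),
                       c("n", "lnVbirthMean", "lnVbirthSd", "vStart",
                         "slope", "intercept", "noiseSd", "mode"))]))
      fit <- fitSizeControl(recs)
      utils::write.csv(
        data.frame(slope = fit@slope, intercept = fit@intercept,
                   se = fit@se, p = fit@p, r2 = fit@r2, n = fit@n),
        file.path(outDir, "size_control.csv"), row.names = FALSE)
      counts$n_records <- nrow(recs)
      counts$slope <- fit@slope
    }
    report$stages[[stage]] <- c(list(seed = sseed), counts)
  }
  jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
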