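## Interchange formats: sweep matrices as CSV with a JSON metadata
## sidecar, run configurations as YAML, results as JSON-ready lists.

#' Write / read sweep sets as CSV + JSON sidecar
#'
#' The CSV holds the time grid in a `time_ms` first column and one
#' `sweep_0001`, `sweep_0002`, ... column per epoch. Acquisition metadata
#' (modality, side, stimulation current, impulse duration, simulation
#' seed) goes to a JSON sidecar at `<path>.json`. Voltages round-trip
#' losslessly to well beyond 6 significant figures.
#'
#' @param sweeps a [SweepSet-class].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `writeSweepCsv` returns `path` invisibly; `readSweepCsv`
#'   returns a [SweepSet-class].
#' @export
writeSweepCsv <- function(sweeps, path) {
  df <- data.frame(time_ms = sweepTimes(sweeps), sweepVoltages(sweeps),
                   check.names = FALSE)
  data.table::fwrite(df, path)
  md <- S4Vectors::metadata(sweeps)
  side <- list(modality = sweeps@modality, side = sweeps@side,
               current_mA = md$current_mA,
               impulse_duration_us = md$impulse_duration_us,
               seed = if (is.na(md$seed)) NULL else md$seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSweepCsv
#' @export
readSweepCsv <- function(path) {
  if (!file.exists(path)) .formatError(sprintf("file not found: %s", path))
  if (file.size(path) == 0) .formatError(sprintf("empty file: %s", path))
  dt <- tryCatch(data.table::fread(path, header = TRUE),
                 error = function(e) .formatError(paste(
                   "could not parse CSV:", conditionMessage(e))))
  if (nrow(dt) == 0 || ncol(dt) < 2)
    .formatError("CSV must contain a time_ms column and at least one sweep column")
  if (names(dt)[1] != "time_ms")
    .formatError(sprintf("first column must be 'time_ms', found '%s'",
                         names(dt)[1]))
  if (anyNA(dt))
    .formatError("CSV contains missing values (ragged rows?)")
  tm <- dt[[1]]
  if (length(tm) >= 2) {
    dtm <- diff(tm)
    bad <- which(abs(dtm - dtm[1]) > 1e-6 * abs(dtm[1]))
    if (length(bad))
      .formatError(sprintf(
        "nonuniform time grid: first bad row %d (time %g ms)",
        bad[1] + 1L, tm[bad[1] + 1L]))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    .formatError(sprintf("metadata sidecar not found: %s", sidecar))
  md <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sweepSet(as.matrix(dt[, -1]), tm, modality = md$modality,
           side = md$side, currentMa = md$current_mA,
           impulseDurationUs = md$impulse_duration_us,
           seed = if (is.null(md$seed)) NA_integer_ else as.integer(md$seed))
}

#' Construct a run configuration
#'
#' @param modality `"median"` or `"tibial"`.
#' @param side `"left"` or `"right"`.
#' @param snr template peak-to-peak over noise RMS, default 3.
#' @param samplingRateHz,epochMs,stimRateHz acquisition geometry;
#'   `epochMs = NULL` picks the modality default (100 / 120 ms).
#' @param latencyJitterSdMs,amplitudeScaleSdFraction sweep variability.
#' @param bandLowHz,bandHighHz recording band, Hz.
#' @param amplitudeFraction,latencyThresholdMs reproducibility criteria.
#' @param ladderCounts descending candidate counts.
#' @param nBaseline baseline measurements, default 5.
#' @param capacity sweeps available per subject.
#' @param seed master seed.
#' @return a [RunConfig-class].
#' @export
runConfig <- function(modality = "median", side = "left", snr = 3,
                      samplingRateHz = 5000, epochMs = NULL,
                      stimRateHz = 4.1, latencyJitterSdMs = 0.3,
                      amplitudeScaleSdFraction = 0.10,
                      bandLowHz = 30, bandHighHz = 500,
                      amplitudeFraction = 0.20, latencyThresholdMs = 0.5,
                      ladderCounts = c(200L, 100L, 50L, 25L, 12L),
                      nBaseline = 5L, capacity = 5000, seed = 1L) {
  if (is.null(epochMs)) epochMs <- defaultEpochMs(modality)
  new("RunConfig", modality = modality, side = side, snr = snr,
      samplingRateHz = samplingRateHz, epochMs = epochMs,
      stimRateHz = stimRateHz, latencyJitterSdMs = latencyJitterSdMs,
      amplitudeScaleSdFraction = amplitudeScaleSdFraction,
      bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      amplitudeFraction = amplitudeFraction,
      latencyThresholdMs = latencyThresholdMs,
      ladderCounts = as.integer(ladderCounts),
      nBaseline = as.integer(nBaseline), capacity = capacity,
      seed = as.integer(seed))
}

.configSlots <- function() {
  setdiff(slotNames("RunConfig"), character(0))
}

#' Serialize run configurations to YAML
#'
#' Writing then reading a configuration reproduces it exactly.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig`
#'   returns a [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  vals <- lapply(.configSlots(), function(s) slot(config, s))
  names(vals) <- .configSlots()
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) .formatError(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  cfg <- runConfig()
  for (s in .configSlots()) {
    if (!s %in% names(vals))
      .formatError(sprintf("config field missing: %s", s))
    slot(cfg, s) <- switch(class(slot(cfg, s)),
      integer = as.integer(vals[[s]]),
      numeric = as.numeric(vals[[s]]),
      vals[[s]])
  }
  cfg
}

#' Serialize a search result for JSON export
#'
#' @param result a [SearchResult-class].
#' @return a plain list ready for [jsonlite::write_json()].
#' @export
searchResultToList <- function(result) {
  list(
    minimal_sweep_count = result@minimalSweepCount,
    baseline_ok = result@baselineOk,
    reduced_below_baseline = result@reducedBelowBaseline,
    sweeps_consumed = result@sweepsConsumed,
    trace = result@trace,
    baseline = lapply(result@baselineMeasurements, .measurementToList),
    final_precision_measurements =
      lapply(result@finalPrecisionMeasurements, .measurementToList))
}

.measurementToList <- function(m) {
  list(modality = m@modality, side = m@side, sweep_count = m@sweepCount,
       peak_latency_ms = m@peakLatencyMs, amplitude_uV = m@amplitudeUV)
}
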