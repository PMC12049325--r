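## Acquisition sources: "perform one measurement with n sweeps" against a
## simulator, a stored sweep set, or a deterministic oracle stub.

.newState <- function() {
  e <- new.env(parent = emptyenv())
  e$consumed <- 0
  e$calls <- 0L
  e
}

#' Simulation-backed acquisition source
#'
#' Generates epochs on demand from a template + noise model; every
#' measurement uses the next block of sweep indices of the same virtual
#' recording, so sweeps are never reused and any prefix is reproducible
#' from the configuration seed alone. Epochs are averaged and the average
#' is band-pass filtered with the noise model's band before peak
#' measurement (filtering and averaging commute, both being linear).
#'
#' @param template an [SEPTemplate-class].
#' @param noise a [NoiseModel-class].
#' @param config a [SimulationConfig-class].
#' @param windows a [PeakWindowConfig-class].
#' @param side `"left"` or `"right"`.
#' @param capacity total sweeps this source can supply (default 5000,
#'   ample for a full baseline + search + precision run).
#' @param filterAverage apply the band-pass to the averaged trace
#'   (default `TRUE`).
#' @return a `SimulatedSource`.
#' @export
#' @examples
#' tpl <- defaultTemplate("median")
#' src <- simulatedSource(tpl, noiseForSNR(tpl, 3),
#'                        simulationConfig(seed = 11))
#' acquireMeasurement(src, 200)
simulatedSource <- function(template, noise, config,
                            windows = defaultWindows(template@modality),
                            side = "left", capacity = 5000,
                            filterAverage = TRUE) {
  new("SimulatedSource", template = template, noise = noise, config = config,
      windows = windows, side = side, capacity = capacity,
      filterAverage = filterAverage, state = .newState())
}

#' Sweep-set-backed acquisition source
#'
#' Serves measurements from a stored [SweepSet-class] (e.g. loaded with
#' [readSweepCsv()]), consuming disjoint blocks of sweeps in order.
#' `filterMode` `"sweep"` filters each epoch before averaging (the
#' acquisition-chain order of a clinical device); `"average"` filters the
#' averaged trace (same result, cheaper); `"none"` skips filtering for
#' already-filtered data.
#'
#' @param sweeps a [SweepSet-class].
#' @param windows a [PeakWindowConfig-class].
#' @param filterMode `"sweep"`, `"average"` or `"none"`.
#' @param bandLowHz,bandHighHz filter band, Hz.
#' @return a `SweepSetSource`.
#' @export
sweepSetSource <- function(sweeps, windows = defaultWindows(sweeps@modality),
                           filterMode = c("sweep", "average", "none"),
                           bandLowHz = 30, bandHighHz = 500) {
  filterMode <- match.arg(filterMode)
  new("SweepSetSource", sweeps = sweeps, windows = windows,
      filterMode = filterMode, bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      state = .newState())
}

#' Deterministic threshold oracle source
#'
#' A stub source that is reproducible exactly at sweep counts at or above
#' a threshold `T`: at counts >= T every measurement has amplitude 2
#' microvolt and latency 20 ms; below T amplitudes alternate between 2 and
#' 3 microvolt (relative difference 0.4, failing the 20% criterion for
#' every consecutive pair). Used to verify the search state machine
#' against brute-force enumeration. Capacity is unlimited.
#'
#' @param threshold smallest reproducible count `T`.
#' @param modality,side labels carried on the stub measurements.
#' @return an `OracleSource`.
#' @export
oracleSource <- function(threshold, modality = "median", side = "left") {
  new("OracleSource", threshold = as.integer(threshold), modality = modality,
      side = side, state = .newState())
}

## -- methods --------------------------------------------------------------

setMethod("sweepsConsumed", "AcquisitionSource",
          function(source) source@state$consumed)

setMethod("sweepsRemaining", "SimulatedSource",
          function(source) source@capacity - source@state$consumed)

setMethod("sweepsRemaining", "SweepSetSource",
          function(source) ncol(source@sweeps) - source@state$consumed)

setMethod("sweepsRemaining", "OracleSource", function(source) Inf)

.checkCapacity <- function(source, n) {
  rem <- sweepsRemaining(source)
  if (n > rem)
    .resourceError(sprintf(
      "measurement with %d sweeps requested but only %s remain (short by %s)",
      n, format(rem), format(n - rem)), shortfall = n - rem, remaining = rem)
}

setMethod("acquireMeasurement", "SimulatedSource", function(source, n) {
  if (n < 1) .sepError("sepsweepInputError", "n must be >= 1")
  .checkCapacity(source, n)
  st <- source@state
  idx <- seq.int(st$consumed + 1, st$consumed + n)
  sim <- .simulateEpochMatrix(source@template, source@noise, source@config, idx)
  v <- rowMeans(sim$voltages)
  if (source@filterAverage && source@noise@rmsUV >= 0)
    v <- bandpassFilter(v, source@config@samplingRateHz,
                        source@noise@bandLowHz, source@noise@bandHighHz)
  ap <- new("AveragedPotential", modality = source@template@modality,
            side = source@side, sweepCount = as.integer(n),
            timeMs = sim$timeMs, voltageUV = v)
  m <- measureSep(ap, source@windows)
  st$consumed <- st$consumed + n
  st$calls <- st$calls + 1L
  m
})

setMethod("acquireMeasurement", "SweepSetSource", function(source, n) {
  if (n < 1) .sepError("sepsweepInputError", "n must be >= 1")
  .checkCapacity(source, n)
  st <- source@state
  fs <- samplingRate(source@sweeps)
  v <- sweepVoltages(source@sweeps)[, (st$consumed + 1):(st$consumed + n),
                                    drop = FALSE]
  if (source@filterMode == "sweep")
    v <- apply(v, 2, bandpassFilter, samplingRateHz = fs,
               lowHz = source@bandLowHz, highHz = source@bandHighHz)
  avg <- rowMeans(as.matrix(v))
  if (source@filterMode == "average")
    avg <- bandpassFilter(avg, fs, source@bandLowHz, source@bandHighHz)
  ap <- new("AveragedPotential", modality = source@sweeps@modality,
            side = source@sweeps@side, sweepCount = as.integer(n),
            timeMs = sweepTimes(source@sweeps), voltageUV = avg)
  m <- measureSep(ap, source@windows)
  st$consumed <- st$consumed + n
  st$calls <- st$calls + 1L
  m
})

setMethod("acquireMeasurement", "OracleSource", function(source, n) {
  if (n < 1) .sepError("sepsweepInputError", "n must be >= 1")
  st <- source@state
  st$calls <- st$calls + 1L
  amp <- if (n >= source@threshold) 2.0 else c(2.0, 3.0)[st$calls %% 2L + 1L]
  st$consumed <- st$consumed + n
  new("SEPMeasurement", modality = source@modality, side = source@side,
      sweepCount = as.integer(n), peakLatencyMs = 20, amplitudeUV = amp,
      negVoltageUV = -amp / 2, posLatencyMs = 25, posVoltageUV = amp / 2)
})

setMethod("show", "SimulatedSource", function(object) {
  cat(sprintf(
    "SimulatedSource: %s/%s, SNR %.2f, %g of %g sweeps consumed\n",
    object@template@modality, object@side,
    templatePeakToPeak(object@template) / object@noise@rmsUV,
    object@state$consumed, object@capacity))
})

setMethod("show", "OracleSource", function(object) {
  cat(sprintf("OracleSource: reproducible iff count >= %d\n",
              object@threshold))
})
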