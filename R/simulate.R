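## Seeded sweep simulator: band-limited Gaussian background noise plus a
## jittered, scaled template waveform, one independent substream per sweep.

## Deterministic seed derivation: mixes a master seed with a string key so
## that every stage/sweep gets its own reproducible substream. All
## arithmetic stays below 2^53, the result below 2^31.
.mixSeed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 1013904223
  as.integer((as.numeric(seed) %% 1013904223 * 2654435 + h * 97 + 17) %%
             2147483629)
}

#' Construct a noise model
#'
#' @param bandLowHz,bandHighHz passband edges in Hz (defaults 30 and 500,
#'   the clinical SEP recording band).
#' @param rmsUV target empirical RMS in microvolt.
#' @param seed integer seed.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(bandLowHz = 30, bandHighHz = 500, rmsUV = 1,
                       seed = 1L) {
  new("NoiseModel", bandLowHz = bandLowHz, bandHighHz = bandHighHz,
      rmsUV = rmsUV, seed = as.integer(seed))
}

#' Construct a simulation configuration
#'
#' @param samplingRateHz sampling rate, default 5000 Hz (comfortably above
#'   twice the 500 Hz band edge).
#' @param epochMs epoch length in ms, default 100.
#' @param stimRateHz stimulation rate, default 4.1 Hz.
#' @param latencyJitterSdMs SD of the per-sweep common latency shift,
#'   default 0.3 ms.
#' @param amplitudeScaleSdFraction SD of the per-sweep amplitude scale
#'   around 1, default 0.10.
#' @param seed integer master seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(samplingRateHz = 5000, epochMs = 100,
                             stimRateHz = 4.1, latencyJitterSdMs = 0.3,
                             amplitudeScaleSdFraction = 0.10, seed = 1L) {
  new("SimulationConfig", samplingRateHz = samplingRateHz, epochMs = epochMs,
      stimRateHz = stimRateHz, latencyJitterSdMs = latencyJitterSdMs,
      amplitudeScaleSdFraction = amplitudeScaleSdFraction,
      seed = as.integer(seed))
}

## Core noise synthesis on an already-seeded RNG stream: white Gaussian
## noise restricted to [lo, hi] Hz by zeroing FFT bins outside the band
## (exact band control, no filter transient), rescaled to the target
## empirical RMS.
.bandNoiseRaw <- function(n, samplingRateHz, lo, hi, rmsUV) {
  if (rmsUV == 0) return(numeric(n))
  w <- stats::rnorm(n)
  freq <- (seq_len(n) - 1) * samplingRateHz / n
  folded <- pmin(freq, samplingRateHz - freq)
  keep <- folded >= lo & folded <= hi
  if (!any(keep))
    .sepError("sepsweepInputError",
              "no frequency bins fall inside the noise band for this epoch length")
  W <- stats::fft(w)
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  x * (rmsUV / r)
}

#' Generate band-limited Gaussian noise
#'
#' White Gaussian noise band-limited to the model's passband and rescaled
#' so its empirical RMS equals `rmsUV` exactly. A pure function of the
#' model's seed: the same model yields the same trace.
#'
#' @param model a [NoiseModel-class].
#' @param nSamples number of samples (> 0).
#' @param samplingRateHz sampling rate; must exceed twice the band's upper
#'   edge.
#' @return numeric vector of length `nSamples`.
#' @export
generateNoise <- function(model, nSamples, samplingRateHz) {
  if (nSamples <= 0)
    .sepError("sepsweepInputError", "nSamples must be > 0")
  if (model@bandHighHz >= samplingRateHz / 2)
    .sepError("sepsweepInputError", sprintf(
      "noise band upper edge (%g Hz) must be below the Nyquist frequency (%g Hz)",
      model@bandHighHz, samplingRateHz / 2))
  if (model@rmsUV == 0) return(numeric(nSamples))
  runif.was <- .Random.seed.save()
  on.exit(.Random.seed.restore(runif.was))
  set.seed(model@seed)
  .bandNoiseRaw(nSamples, samplingRateHz, model@bandLowHz, model@bandHighHz,
                model@rmsUV)
}

## Save/restore the global RNG state so seeded generators do not disturb
## the caller's stream.
.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

.timeGrid <- function(config) {
  n <- floor(config@epochMs * config@samplingRateHz / 1000)
  (seq_len(n) - 1) / config@samplingRateHz * 1000
}

## Simulate the epochs with the given sweep indices (1-based). Each sweep's
## jitter, amplitude scale and noise come from its own substream derived
## from (config seed, sweep index), so any subset is reproducible.
.simulateEpochMatrix <- function(template, noise, config, indices) {
  tm <- .timeGrid(config)
  n <- length(tm)
  if (noise@rmsUV > 0 && config@samplingRateHz < 2 * noise@bandHighHz)
    .sepError("sepsweepInputError",
              "samplingRateHz must be at least twice the noise band upper edge")
  rngState <- .Random.seed.save()
  on.exit(.Random.seed.restore(rngState))
  out <- matrix(0, nrow = n, ncol = length(indices))
  for (k in seq_along(indices)) {
    set.seed(.mixSeed(config@seed, "sweep", indices[k]))
    jit <- stats::rnorm(1, 0, config@latencyJitterSdMs)
    sc <- stats::rnorm(1, 1, config@amplitudeScaleSdFraction)
    ns <- if (noise@rmsUV > 0)
      .bandNoiseRaw(n, config@samplingRateHz, noise@bandLowHz,
                    noise@bandHighHz, noise@rmsUV)
    else numeric(n)
    out[, k] <- sc * templateWaveform(template, tm, latencyShiftMs = jit) + ns
  }
  list(timeMs = tm, voltages = out)
}

#' Construct a sweep set
#'
#' @param voltages numeric matrix, rows = time points, columns = sweeps.
#' @param timeMs uniform time grid starting at 0, ms.
#' @param modality `"median"` or `"tibial"`.
#' @param side `"left"` or `"right"`.
#' @param currentMa stimulation current; defaults to 15 mA for median and
#'   30 mA for tibial stimulation.
#' @param impulseDurationUs stimulus impulse duration, default 200 us.
#' @param seed simulation seed recorded in the metadata (`NA` for
#'   recorded data).
#' @return a [SweepSet-class].
#' @export
sweepSet <- function(voltages, timeMs, modality, side = "left",
                     currentMa = NULL, impulseDurationUs = 200,
                     seed = NA_integer_) {
  voltages <- as.matrix(voltages)
  if (nrow(voltages) != length(timeMs))
    .sepError("sepsweepInputError",
              "voltages must have one row per time point")
  if (is.null(currentMa))
    currentMa <- if (identical(modality, "median")) 15 else 30
  colnames(voltages) <- sprintf("sweep_%04d", seq_len(ncol(voltages)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(voltage = voltages),
    rowData = S4Vectors::DataFrame(time_ms = timeMs),
    metadata = list(current_mA = currentMa,
                    impulse_duration_us = impulseDurationUs,
                    seed = seed))
  new("SweepSet", se, modality = modality, side = side)
}

#' Generate a set of simulated sweeps
#'
#' Each epoch is the template waveform with a per-sweep common latency
#' shift `~ Normal(0, latencyJitterSdMs)` applied to all components
#' jointly, a per-sweep amplitude scale `~ Normal(1,
#' amplitudeScaleSdFraction)`, plus fresh band-limited noise. Sweep-level
#' randomness is a pure function of `(config seed, sweep index)`: the same
#' sweep index always yields the same epoch regardless of how many sweeps
#' are requested.
#'
#' @param template an [SEPTemplate-class].
#' @param noise a [NoiseModel-class].
#' @param config a [SimulationConfig-class].
#' @param nSweeps number of epochs (>= 1).
#' @param side `"left"` or `"right"`.
#' @param firstSweep index of the first sweep to generate (default 1);
#'   lets callers materialize later blocks of the same virtual recording.
#' @return a [SweepSet-class].
#' @export
#' @examples
#' tpl <- defaultTemplate("median")
#' nm <- noiseModel(rmsUV = templatePeakToPeak(tpl) / 3)
#' ss <- generateSweepSet(tpl, nm, simulationConfig(seed = 7), 20)
#' dim(ss)
generateSweepSet <- function(template, noise, config, nSweeps,
                             side = "left", firstSweep = 1L) {
  if (nSweeps < 1) .sepError("sepsweepInputError", "nSweeps must be >= 1")
  idx <- seq.int(firstSweep, firstSweep + nSweeps - 1L)
  sim <- .simulateEpochMatrix(template, noise, config, idx)
  sweepSet(sim$voltages, sim$timeMs, template@modality, side = side,
           seed = config@seed)
}

#' Noise model matched to a target SNR
#'
#' SNR is defined as template peak-to-peak amplitude over noise RMS; this
#' helper returns a [NoiseModel-class] whose RMS realizes the requested
#' SNR for the given template.
#'
#' @param template an [SEPTemplate-class].
#' @param snr target signal-to-noise ratio (> 0).
#' @param bandLowHz,bandHighHz passband, Hz.
#' @param seed integer seed.
#' @return a [NoiseModel-class].
#' @export
noiseForSNR <- function(template, snr, bandLowHz = 30, bandHighHz = 500,
                        seed = 1L) {
  if (snr <= 0) .sepError("sepsweepInputError", "snr must be > 0")
  noiseModel(bandLowHz, bandHighHz, rmsUV = templatePeakToPeak(template) / snr,
             seed = seed)
}

## SweepSet accessors ------------------------------------------------------

#' @describeIn sweepSet the shared time grid (ms).
#' @param x a [SweepSet-class].
#' @export
sweepTimes <- function(x) SummarizedExperiment::rowData(x)$time_ms

#' @describeIn sweepSet the voltage matrix (time x sweeps, microvolt).
#' @export
sweepVoltages <- function(x) SummarizedExperiment::assay(x, "voltage")

#' @describeIn sweepSet number of sweeps in the set.
#' @export
nSweeps <- function(x) ncol(x)

#' @describeIn sweepSet sampling rate implied by the time grid, Hz.
#' @export
samplingRate <- function(x) {
  tm <- sweepTimes(x)
  1000 / (tm[2] - tm[1])
}

#' @rdname accessors
setMethod("modality", "SweepSet", function(x) x@modality)
#' @rdname accessors
setMethod("side", "SweepSet", function(x) x@side)

setMethod("show", "SweepSet", function(object) {
  tm <- sweepTimes(object)
  cat(sprintf(
    "SweepSet: %d sweeps, %s nerve, %s side\n  %d samples / epoch (0-%.1f ms @ %.0f Hz)\n",
    ncol(object), object@modality, object@side, nrow(object),
    max(tm), samplingRate(object)))
  md <- S4Vectors::metadata(object)
  cat(sprintf("  stimulation: %g mA, %g us impulse\n",
              md$current_mA, md$impulse_duration_us))
})
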