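# Fixtures built in code: templates, noiseless potentials, seeded sources.

fixtureTemplate <- function(modality = "median") defaultTemplate(modality)

# a single-component template whose peak is analytically at its center
singleBumpTemplate <- function(mu = 20, sigma = 2, amp = 2) {
  sepTemplate("median", data.frame(
    label = "N20", polarity = "negative", latency_ms = mu,
    width_ms = sigma, amplitude_uV = amp))
}

zeroTemplate <- function(modality = "median") {
  sepTemplate(modality, data.frame(
    label = character(), polarity = character(), latency_ms = numeric(),
    width_ms = numeric(), amplitude_uV = numeric()))
}

# noiseless averaged potential straight from a template waveform
templatePotential <- function(template, epochMs = 100, fs = 5000,
                              sweepCount = 1L, scale = 1, shiftMs = 0) {
  tm <- (seq_len(floor(epochMs * fs / 1000)) - 1) / fs * 1000
  new("AveragedPotential", modality = template@modality, side = "left",
      sweepCount = as.integer(sweepCount), timeMs = tm,
      voltageUV = scale * templateWaveform(template, tm,
                                           latencyShiftMs = shiftMs))
}

# measurement stub for reproducibility tests
stubMeasurement <- function(amplitude, latency, modality = "median",
                            side = "left", count = 200L) {
  new("SEPMeasurement", modality = modality, side = side,
      sweepCount = as.integer(count), peakLatencyMs = latency,
      amplitudeUV = amplitude, negVoltageUV = -amplitude / 2,
      posLatencyMs = latency + 5, posVoltageUV = amplitude / 2)
}

# deterministic seed derivation for replicate loops in tests
.mixSeedForTest <- function(seed, ...) {
  v <- c(...)
  as.integer((seed * 7919 + sum(v * seq_along(v)) * 104729) %% 2147483647)
}

defaultSimSource <- function(snr = 3, seed = 1L, modality = "median",
                             capacity = 5000, ...) {
  tpl <- defaultTemplate(modality)
  simulatedSource(tpl, noiseForSNR(tpl, snr, seed = seed),
                  simulationConfig(epochMs = defaultEpochMs(modality),
                                   seed = seed, ...),
                  capacity = capacity)
}
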