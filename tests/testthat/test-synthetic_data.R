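# Simulator: template waveforms, band-limited noise, sweep generation.

test_that("template waveform is the signed sum of Gaussian bumps", {
  tm <- seq(0, 100, by = 0.2)
  expect_equal(templateWaveform(zeroTemplate(), tm), rep(0, length(tm)))

  tpl <- singleBumpTemplate(mu = 20, sigma = 2, amp = 2)
  v <- templateWaveform(tpl, tm)
  expect_equal(v[tm == 20], -2.0)
  # analytic Gaussian at a half-width point
  expect_equal(v[tm == 22], -2 * exp(-1 / 2))

  expect_error(templateWaveform(tpl, numeric(0)), "empty")
})

test_that("default template peaks sit at the nominal latencies", {
  # dense-grid oracle, independent of detectPeak
  for (modality in c("median", "tibial")) {
    tpl <- defaultTemplate(modality)
    tm <- seq(0, 120, by = 0.001)
    v <- templateWaveform(tpl, tm)
    nominal <- if (modality == "median") c(20, 25) else c(37, 40)
    expect_equal(tm[which.min(v)], nominal[1], tolerance = 1e-3)
    expect_equal(tm[which.max(v)], nominal[2], tolerance = 1e-3)
    # templatePeaks agrees with the dense grid
    pk <- templatePeaks(tpl)
    expect_equal(pk$latency_ms, nominal, tolerance = 1e-3)
    expect_equal(pk$voltage_uV, c(min(v), max(v)), tolerance = 1e-6)
  }
})

test_that("template validity enforces ordering, labels and positivity", {
  expect_error(sepTemplate("median", data.frame(
    label = c("N20", "P25"), polarity = c("negative", "positive"),
    latency_ms = c(25, 20), width_ms = c(2, 2), amplitude_uV = c(2, 1))),
    "strictly increasing")
  expect_error(sepTemplate("median", data.frame(
    label = c("A", "B"), polarity = c("negative", "positive"),
    latency_ms = c(20, 25), width_ms = c(2, 2), amplitude_uV = c(2, 1))),
    "N20")
  expect_error(sepTemplate("tibial", data.frame(
    label = c("N37", "P40"), polarity = c("negative", "positive"),
    latency_ms = c(37, 40), width_ms = c(-1, 2), amplitude_uV = c(2, 1))),
    "width")
})

test_that("band-limited noise has the requested RMS and stays in band", {
  nm <- noiseModel(30, 500, rmsUV = 1, seed = 42L)
  x <- generateNoise(nm, 50000, 5000)
  expect_equal(sqrt(mean(x^2)), 1.0, tolerance = 0.01)

  # periodogram oracle: fraction of power outside [30, 500] Hz
  pg <- Mod(fft(x))^2
  freq <- (seq_along(x) - 1) * 5000 / length(x)
  folded <- pmin(freq, 5000 - freq)
  outside <- sum(pg[folded < 30 | folded > 500]) / sum(pg)
  expect_lt(outside, 0.05)

  # determinism and zero-RMS degenerate case
  expect_identical(x, generateNoise(nm, 50000, 5000))
  expect_identical(generateNoise(noiseModel(rmsUV = 0), 100, 5000),
                   numeric(100))
  # invalid band vs Nyquist
  expect_error(generateNoise(noiseModel(30, 500, 1, 1L), 100, 800),
               "Nyquist")
})

test_that("sweep generation is a pure function of (seed, sweep index)", {
  tpl <- fixtureTemplate()
  nm <- noiseForSNR(tpl, 3, seed = 7L)
  cfg <- simulationConfig(seed = 7L)

  a <- generateSweepSet(tpl, nm, cfg, 50)
  b <- generateSweepSet(tpl, nm, cfg, 80)
  expect_identical(sweepVoltages(a)[, 37], sweepVoltages(b)[, 37])

  # degenerate case: no jitter, no scale spread, no noise => every epoch
  # equals the template waveform
  quiet <- generateSweepSet(tpl, noiseModel(rmsUV = 0),
                            simulationConfig(latencyJitterSdMs = 0,
                                             amplitudeScaleSdFraction = 0,
                                             seed = 1L), 5)
  ref <- templateWaveform(tpl, sweepTimes(quiet))
  for (i in 1:5) expect_equal(sweepVoltages(quiet)[, i], ref)

  expect_error(generateSweepSet(tpl, nm, cfg, 0), "nSweeps")
  expect_error(simulationConfig(latencyJitterSdMs = -1), "Jitter|>= 0")
})

test_that("mean of many jittered noisy sweeps recovers the template peak", {
  tpl <- fixtureTemplate()
  errs <- vapply(1:15, function(k) {
    seed <- .mixSeedForTest(11L, k)
    ss <- generateSweepSet(tpl, noiseForSNR(tpl, 3, seed = seed),
                           simulationConfig(seed = seed), 200)
    pk <- detectPeak(averageSweeps(ss, 200), 15, 28, "negative")
    abs(pk$latency_ms - 20)
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("epoch cannot outlast the inter-stimulus interval", {
  expect_error(simulationConfig(epochMs = 300), "inter-stimulus")
  # 243.9 ms fits at 4.1 Hz
  expect_s4_class(simulationConfig(epochMs = 240), "SimulationConfig")
})

test_that("ground-truth latency is recovered at good SNR", {
  # at SNR >= 5 and 200 averaged sweeps, the measured N20 latency stays
  # within 0.5 ms of the template latency in at least 95% of replicates
  hits <- 0L
  reps <- 100
  for (k in seq_len(reps)) {
    src <- defaultSimSource(snr = 5, seed = .mixSeedForTest(8L, k))
    m <- acquireMeasurement(src, 200)
    if (abs(peakLatency(m) - 20) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("averaging noise-only epochs follows the 1/sqrt(n) law", {
  # quick per-module check at modest replicate count; the full-scale study
  # is in the acceptance suite
  nm <- noiseModel(rmsUV = 1, seed = 1L)
  cfg <- simulationConfig(seed = 13L)
  reps <- 30
  for (n in c(10, 40)) {
    r <- numeric(reps)
    for (k in seq_len(reps)) {
      cfgk <- simulationConfig(seed = .mixSeedForTest(13L, n, k))
      ss <- generateSweepSet(zeroTemplate(), nm, cfgk, n)
      r[k] <- sqrt(mean(rowMeans(sweepVoltages(ss))^2))
    }
    expect_equal(mean(r) * sqrt(n), 1, tolerance = 0.15)
  }
})
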