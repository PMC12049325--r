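# Signal chain: filtering, averaging, peak detection, measurement.

test_that("band-pass filter preserves in-band and rejects out-of-band tones", {
  fs <- 5000
  t <- seq(0, 1, by = 1 / fs)
  inBand <- sin(2 * pi * 100 * t)
  outBand <- sin(2 * pi * 5 * t)
  mid <- seq(1000, length(t) - 1000)   # away from edge transients

  yIn <- bandpassFilter(inBand, fs)
  expect_equal(max(abs(yIn[mid])), 1, tolerance = 0.05)

  yOut <- bandpassFilter(outBand, fs)
  expect_lt(max(abs(yOut[mid])), 0.1)

  expect_equal(bandpassFilter(rep(0, 500), fs), rep(0, 500))
  expect_error(bandpassFilter(rnorm(500), fs, 500, 30), "invalid band")
  expect_error(bandpassFilter(rnorm(500), fs, 30, 3000), "invalid band")
  expect_error(bandpassFilter(rnorm(10), fs), "warm-up")
})

test_that("averaging is the sample-wise mean over the requested block", {
  tpl <- fixtureTemplate()
  tm <- (0:499) / 5
  v <- templateWaveform(tpl, tm)
  ss <- sweepSet(cbind(v, v, v), tm, "median")
  avg <- averageSweeps(ss, 3)
  expect_equal(avg@voltageUV, unname(v))
  expect_equal(sweepCount(avg), 3L)

  # n = 1 returns the epoch unchanged; {+v, -v} averages to zero
  expect_equal(averageSweeps(ss, 1)@voltageUV, unname(v))
  pm <- sweepSet(cbind(v, -v), tm, "median")
  expect_equal(averageSweeps(pm, 2)@voltageUV, rep(0, length(v)))

  # linearity: average(a * X) = a * average(X)
  ss2 <- sweepSet(3.5 * cbind(v, 2 * v), tm, "median")
  ss1 <- sweepSet(cbind(v, 2 * v), tm, "median")
  expect_equal(averageSweeps(ss2, 2)@voltageUV,
               3.5 * averageSweeps(ss1, 2)@voltageUV)

  # insufficient epochs: error names the available count
  expect_error(averageSweeps(ss, 5), "3 are available",
               class = "sepResourceError")
  expect_error(averageSweeps(ss, 2, offset = 2), class = "sepResourceError")
})

test_that("filter and average commute (both linear)", {
  tpl <- fixtureTemplate()
  ss <- generateSweepSet(tpl, noiseForSNR(tpl, 3, seed = 5L),
                         simulationConfig(seed = 5L), 20)
  fs <- samplingRate(ss)
  avgThenFilter <- bandpassFilter(averageSweeps(ss, 20)@voltageUV, fs)
  filterThenAvg <- averageSweeps(filterSweepSet(ss), 20)@voltageUV
  expect_lt(max(abs(avgThenFilter - filterThenAvg)), 1e-9)
})

test_that("peak detection finds and refines windowed extrema", {
  tpl <- singleBumpTemplate(mu = 20, sigma = 2, amp = 2)
  ap <- templatePotential(tpl)

  pk <- detectPeak(ap, 15, 28, "negative")
  expect_true(pk$interior)
  expect_equal(pk$latency_ms, 20, tolerance = 0.05)
  expect_equal(pk$voltage_uV, -2, tolerance = 0.02)

  # antisymmetry: sign-flipped trace with flipped polarity
  flip <- ap; flip@voltageUV <- -flip@voltageUV
  pk2 <- detectPeak(flip, 15, 28, "positive")
  expect_equal(pk2$latency_ms, pk$latency_ms)
  expect_equal(pk2$voltage_uV, -pk$voltage_uV)

  # constant trace: edge-only result, flagged
  flat <- ap; flat@voltageUV <- rep(1, length(flat@voltageUV))
  pk3 <- detectPeak(flat, 15, 28, "negative")
  expect_false(pk3$interior)

  expect_error(detectPeak(ap, 200, 210, "negative"), ">= 3")
})

test_that("measureSep reduces a potential to latency and peak-to-peak amplitude", {
  for (modality in c("median", "tibial")) {
    tpl <- defaultTemplate(modality)
    ap <- templatePotential(tpl, epochMs = defaultEpochMs(modality))
    m <- measureSep(ap)
    oracle <- templatePeaks(tpl)
    expect_equal(peakLatency(m), oracle$latency_ms[1], tolerance = 0.05)
    expect_equal(amplitude(m),
                 oracle$voltage_uV[2] - oracle$voltage_uV[1],
                 tolerance = 0.02 * amplitude(m))
  }
})

test_that("measurement is linear in scale and equivariant under shift", {
  tpl <- fixtureTemplate()
  m1 <- measureSep(templatePotential(tpl))
  m2 <- measureSep(templatePotential(tpl, scale = 2))
  expect_equal(amplitude(m2), 2 * amplitude(m1), tolerance = 1e-6)
  expect_equal(peakLatency(m2), peakLatency(m1))

  m3 <- measureSep(templatePotential(tpl, shiftMs = 1))
  expect_equal(peakLatency(m3), peakLatency(m1) + 1, tolerance = 0.02)
  expect_equal(amplitude(m3), amplitude(m1), tolerance = 1e-3 * amplitude(m1))

  # amplitude invariant under constant offset
  ap <- templatePotential(tpl)
  ap@voltageUV <- ap@voltageUV + 10
  m4 <- measureSep(ap)
  expect_equal(amplitude(m4), amplitude(m1), tolerance = 1e-9)
})

test_that("measurement failure is distinct from reproducibility failure", {
  flat <- templatePotential(zeroTemplate())
  expect_error(measureSep(flat), class = "sepMeasurementError")
})
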