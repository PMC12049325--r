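# The descending-ladder search with single-ascent recovery.

test_that("ladder defaults and terminal set", {
  lad <- sweepLadder()
  expect_identical(lad@counts, c(200L, 100L, 50L, 25L, 12L))
  expect_identical(terminalCounts(lad),
                   c(12L, 18L, 25L, 37L, 50L, 75L, 100L, 150L, 200L))
  expect_error(sweepLadder(c(100, 200, 50)), "decreasing")
  expect_error(sweepLadder(c(200, 100), intermediate = function(u, l) u + 1),
               "strictly between")
})

test_that("baseline check passes clean sources and rejects bad ones", {
  # noiseless source: five near-identical measurements
  src <- defaultSimSource(seed = 2L)
  src@noise@rmsUV <- 0
  ms <- baselineCheck(src)
  expect_length(ms, 5)
  amps <- vapply(ms, amplitude, numeric(1))
  expect_lt(diff(range(amps)) / mean(amps), 0.05)

  # signal-free source: feasibility error (flat/unstable potentials)
  tplZero <- zeroTemplate()
  srcZero <- simulatedSource(tplZero, noiseModel(rmsUV = 1, seed = 3L),
                             simulationConfig(seed = 3L),
                             windows = defaultWindows("median"))
  expect_error(baselineCheck(srcZero), class = "sepFeasibilityError")

  # source with too few sweeps: resource error naming the shortfall
  small <- defaultSimSource(seed = 4L, capacity = 900)
  expect_error(baselineCheck(small), "short by 100",
               class = "sepResourceError")
})

test_that("state machine follows the hand-traced paths", {
  # reproducible at every count >= 23: descend 100, 50, 25; fail 12;
  # fail intermediate 18; settle at 25
  res <- runSweepReduction(oracleSource(23))
  expect_identical(minimalSweepCount(res), 25L)
  tr <- searchTrace(res)
  expect_identical(tr$count, c(200L, 100L, 50L, 25L, 12L, 18L))
  expect_identical(tr$reproducible, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(tr$phase,
                   c("baseline", "descent", "descent", "descent", "descent",
                     "ascent"))

  # reproducible everywhere: ladder minimum, no ascent
  res2 <- runSweepReduction(oracleSource(1))
  expect_identical(minimalSweepCount(res2), 12L)
  expect_false(any(searchTrace(res2)$phase == "ascent"))

  # fails at 100, passes the intermediate 150
  res3 <- runSweepReduction(oracleSource(150))
  expect_identical(minimalSweepCount(res3), 150L)
  expect_identical(searchTrace(res3)$count, c(200L, 100L, 150L))
  expect_true(res3@reducedBelowBaseline)

  # never reproducible below baseline
  res4 <- runSweepReduction(oracleSource(200))
  expect_identical(minimalSweepCount(res4), 200L)
  expect_false(res4@reducedBelowBaseline)
})

test_that("oracle equivalence: result is the smallest terminal count >= T", {
  terminals <- terminalCounts(sweepLadder())
  for (T in 1:200) {
    got <- minimalSweepCount(runSweepReduction(oracleSource(T)))
    expect_identical(got, min(terminals[terminals >= T]),
                     info = sprintf("T = %d", T))
  }
})

test_that("trace invariants and sweep accounting hold on stochastic runs", {
  for (seed in c(21L, 22L, 23L)) {
    src <- defaultSimSource(snr = 3, seed = seed)
    res <- tryCatch(findMinimalSweepCount(src),
                    sepFeasibilityError = function(e) NULL)
    if (is.null(res)) next
    k <- minimalSweepCount(res)
    tr <- searchTrace(res)
    expect_true(k %in% terminalCounts(sweepLadder()))
    expect_true(any(tr$count == k & tr$reproducible))
    expect_false(any(tr$count < k & tr$reproducible))
    # total sweeps: 5 x 200 baseline + 2 per tested count + 3 x minimal
    expected <- 5 * 200 + sum(2 * tr$count[tr$phase != "baseline"]) + 3 * k
    expect_equal(res@sweepsConsumed, expected)
    expect_equal(sweepsConsumed(src), expected)
  }
})

test_that("precision measurements are fresh, at the minimal count, reproducible by seed", {
  src <- defaultSimSource(snr = 6, seed = 31L)
  res <- findMinimalSweepCount(src)
  expect_length(res@finalPrecisionMeasurements, 3)
  counts <- vapply(res@finalPrecisionMeasurements, sweepCount, integer(1))
  expect_true(all(counts == minimalSweepCount(res)))

  # identical source/seed: identical outcome, byte-for-byte
  src2 <- defaultSimSource(snr = 6, seed = 31L)
  res2 <- findMinimalSweepCount(src2)
  expect_identical(searchResultToList(res), searchResultToList(res2))

  # fully degenerate source (no noise, no jitter, no scale spread):
  # the three amplitudes identical, precision 0
  quiet <- defaultSimSource(seed = 32L, latencyJitterSdMs = 0,
                            amplitudeScaleSdFraction = 0)
  quiet@noise@rmsUV <- 0
  resQ <- findMinimalSweepCount(quiet)
  ampsQ <- vapply(resQ@finalPrecisionMeasurements, amplitude, numeric(1))
  expect_equal(precision(ampsQ), 0, tolerance = 1e-6)
})

test_that("source exhaustion mid-search carries the partial trace", {
  src <- defaultSimSource(snr = 6, seed = 41L, capacity = 1150)
  err <- tryCatch(runSweepReduction(src), sepResourceError = function(e) e)
  expect_s3_class(err, "sepResourceError")
  expect_true(!is.null(err$partialTrace))
  expect_true(nrow(err$partialTrace) >= 1)
})
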