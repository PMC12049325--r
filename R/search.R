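## The sweep-count reduction search: five baseline measurements at the
## standard count establish feasibility, then the candidate ladder is
## descended (two fresh measurements per count); the first failure
## triggers a single intermediate (ascent) test that decides between the
## midpoint and the last reproducible level; finally three more
## measurements at the minimal count quantify precision.

#' Construct a sweep-count ladder
#'
#' @param counts strictly decreasing candidate counts; the first element
#'   is the baseline count. Default `c(200, 100, 50, 25, 12)`: 200 to 100
#'   to 50 are the protocol's explicit steps and the halving continues to
#'   the 25- and 12-sweep levels seen in reduced recordings.
#' @param intermediate rule producing the single ascent count tested
#'   between two adjacent levels after a failure; default the integer
#'   midpoint `floor((upper + lower) / 2)`, i.e. 150, 75, 37, 18.
#' @return a [SweepLadder-class].
#' @export
sweepLadder <- function(counts = c(200L, 100L, 50L, 25L, 12L),
                        intermediate = function(upper, lower)
                          as.integer(floor((upper + lower) / 2))) {
  new("SweepLadder", counts = as.integer(counts), intermediate = intermediate)
}

#' @describeIn sweepLadder all counts at which the search can terminate:
#'   the ladder levels plus every intermediate count. For the default
#'   ladder: 12, 18, 25, 37, 50, 75, 100, 150, 200.
#' @param ladder a [SweepLadder-class].
#' @export
terminalCounts <- function(ladder) {
  k <- ladder@counts
  mids <- vapply(seq_len(length(k) - 1L),
                 function(i) ladder@intermediate(k[i], k[i + 1L]), integer(1))
  sort(unique(c(k, mids)))
}

.emptyTrace <- function() {
  data.frame(count = integer(), phase = character(), reproducible = logical(),
             amplitude1_uV = numeric(), amplitude2_uV = numeric(),
             latency1_ms = numeric(), latency2_ms = numeric(),
             stringsAsFactors = FALSE)
}

.traceRow <- function(count, phase, ok, m1, m2) {
  data.frame(count = as.integer(count), phase = phase, reproducible = ok,
             amplitude1_uV = m1@amplitudeUV, amplitude2_uV = m2@amplitudeUV,
             latency1_ms = m1@peakLatencyMs, latency2_ms = m2@peakLatencyMs,
             stringsAsFactors = FALSE)
}

## Acquire two fresh measurements at `count` and test the criterion.
## A measurement failure (peak not found) counts as not reproducible.
.testCount <- function(source, count, criteria) {
  m1 <- acquireMeasurement(source, count)
  m2 <- acquireMeasurement(source, count)
  ok <- tryCatch(isReproducible(m1, m2, criteria),
                 sepMeasurementError = function(e) FALSE)
  list(ok = ok, m1 = m1, m2 = m2)
}

#' Baseline feasibility check
#'
#' Performs `nBaseline` (default 5) measurements at the baseline count
#' (default 200) and verifies they are consecutively reproducible. A
#' subject whose potentials are not reproducible at the standard count is
#' not a candidate for sweep reduction: the check raises a distinct
#' feasibility error. Measurement failures (flat or absent potentials)
#' also surface as feasibility errors.
#'
#' @param source an [AcquisitionSource-class].
#' @param criteria a [ReproducibilityCriteria-class].
#' @param nBaseline number of baseline measurements, default 5.
#' @param baselineCount sweep count of the baseline measurements,
#'   default 200.
#' @return list of `nBaseline` [SEPMeasurement-class] objects.
#' @export
baselineCheck <- function(source, criteria = reproducibilityCriteria(),
                          nBaseline = 5L, baselineCount = 200L) {
  need <- nBaseline * baselineCount
  rem <- sweepsRemaining(source)
  if (need > rem)
    .resourceError(sprintf(
      "baseline needs %d sweeps (%d x %d) but only %s are available (short by %s)",
      need, nBaseline, baselineCount, format(rem), format(need - rem)),
      shortfall = need - rem, remaining = rem)
  ms <- vector("list", nBaseline)
  for (i in seq_len(nBaseline)) {
    ms[[i]] <- tryCatch(acquireMeasurement(source, baselineCount),
      sepMeasurementError = function(e) .feasibilityError(paste(
        "baseline measurement failed:", conditionMessage(e))))
  }
  ok <- tryCatch(allConsecutiveReproducible(ms, criteria),
                 sepMeasurementError = function(e) FALSE)
  if (!ok)
    .feasibilityError(sprintf(
      "potentials are not reproducible at the baseline count (%d sweeps); the reduction algorithm is not applicable",
      baselineCount))
  ms
}

#' Run the sweep-count reduction search
#'
#' Descends the ladder from the level below baseline. At each candidate
#' count two fresh measurements are acquired and tested; on the first
#' failure at count `c` with last reproducible level `u`, the single
#' intermediate count `m = intermediate(u, c)` is tested: the result is
#' `m` if reproducible there, else `u`. If the whole ladder is descended
#' without failure the result is the ladder minimum. The trace records
#' every tested count in order.
#'
#' @param source an [AcquisitionSource-class].
#' @param criteria a [ReproducibilityCriteria-class].
#' @param ladder a [SweepLadder-class].
#' @param baseline baseline measurements from [baselineCheck()]; if
#'   `NULL`, the baseline check is run first (consuming
#'   `nBaseline x baseline count` sweeps from the source).
#' @param nBaseline baseline measurements when `baseline` is `NULL`.
#' @return a [SearchResult-class] (precision measurements not yet
#'   attached; see [completeWithPrecisionMeasurements()]).
#' @export
#' @examples
#' res <- runSweepReduction(oracleSource(23))
#' minimalSweepCount(res)   # 25: smallest terminal count >= 23
#' searchTrace(res)
runSweepReduction <- function(source, criteria = reproducibilityCriteria(),
                              ladder = sweepLadder(), baseline = NULL,
                              nBaseline = 5L) {
  counts <- ladder@counts
  baselineCount <- counts[1L]
  if (is.null(baseline))
    baseline <- baselineCheck(source, criteria, nBaseline = nBaseline,
                              baselineCount = baselineCount)
  trace <- .traceRow(baselineCount, "baseline", TRUE,
                     baseline[[1L]], baseline[[2L]])
  wrapResource <- function(expr) {
    tryCatch(expr, sepResourceError = function(e) {
      e$partialTrace <- trace
      stop(e)
    })
  }
  u <- baselineCount
  minimal <- NA_integer_
  for (i in seq.int(2L, length(counts))) {
    c_i <- counts[i]
    t1 <- wrapResource(.testCount(source, c_i, criteria))
    trace <- rbind(trace, .traceRow(c_i, "descent", t1$ok, t1$m1, t1$m2))
    if (t1$ok) {
      u <- c_i
      next
    }
    m <- ladder@intermediate(u, c_i)
    t2 <- wrapResource(.testCount(source, m, criteria))
    trace <- rbind(trace, .traceRow(m, "ascent", t2$ok, t2$m1, t2$m2))
    minimal <- if (t2$ok) m else u
    break
  }
  if (is.na(minimal)) minimal <- counts[length(counts)]
  new("SearchResult", minimalSweepCount = as.integer(minimal),
      baselineOk = TRUE, trace = trace,
      reducedBelowBaseline = minimal < baselineCount,
      baselineMeasurements = baseline,
      finalPrecisionMeasurements = list(),
      sweepsConsumed = nBaseline * baselineCount +
        sum(2 * trace$count[trace$phase != "baseline"]))
}

#' Append the three precision measurements
#'
#' After the minimal count is found, three more measurements at that count
#' are acquired; their amplitudes feed the precision statistic (standard
#' error of the repeated amplitudes).
#'
#' @param source the same [AcquisitionSource-class] the search ran on.
#' @param result a [SearchResult-class].
#' @return the result with `finalPrecisionMeasurements` of length 3 and
#'   updated sweep accounting.
#' @export
completeWithPrecisionMeasurements <- function(source, result) {
  k <- result@minimalSweepCount
  ms <- lapply(1:3, function(i) acquireMeasurement(source, k))
  result@finalPrecisionMeasurements <- ms
  result@sweepsConsumed <- result@sweepsConsumed + 3 * k
  result
}

#' One-call search
#'
#' Baseline check, ladder descent and precision measurements in sequence:
#' the complete per-subject protocol.
#'
#' @inheritParams runSweepReduction
#' @return a completed [SearchResult-class].
#' @export
findMinimalSweepCount <- function(source,
                                  criteria = reproducibilityCriteria(),
                                  ladder = sweepLadder(), nBaseline = 5L) {
  res <- runSweepReduction(source, criteria, ladder, nBaseline = nBaseline)
  completeWithPrecisionMeasurements(source, res)
}

## accessors ---------------------------------------------------------------

#' @describeIn runSweepReduction the minimal reproducible sweep count.
#' @param result a [SearchResult-class].
#' @export
minimalSweepCount <- function(result) result@minimalSweepCount

#' @describeIn runSweepReduction the full decision trace (`data.frame`).
#' @export
searchTrace <- function(result) result@trace

setMethod("show", "SearchResult", function(object) {
  cat(sprintf(
    "SearchResult: minimal sweep count %d (%s baseline)\n",
    object@minimalSweepCount,
    if (object@reducedBelowBaseline) "reduced below" else "equal to"))
  cat(sprintf("  sweeps consumed: %g; trace:\n", object@sweepsConsumed))
  print(object@trace, row.names = FALSE)
})
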