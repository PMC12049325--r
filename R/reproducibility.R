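## The reproducibility criterion: the predicate driving every branch of
## the sweep-count reduction algorithm.

#' Construct reproducibility criteria
#'
#' Defaults follow the clinical criterion: amplitudes must differ by less
#' than 20% and latencies by less than 0.5 ms. Both comparisons are
#' strict; the thresholds are configurable for sensitivity analyses
#' (e.g. tightening the amplitude criterion to 10%).
#'
#' @param amplitudeFraction relative amplitude threshold in (0, 1),
#'   default 0.20.
#' @param latencyMs latency threshold in ms (> 0), default 0.5.
#' @return a [ReproducibilityCriteria-class].
#' @export
reproducibilityCriteria <- function(amplitudeFraction = 0.20, latencyMs = 0.5) {
  new("ReproducibilityCriteria", amplitudeFraction = amplitudeFraction,
      latencyMs = latencyMs)
}

#' Relative amplitude difference
#'
#' `|a1 - a2| / mean(a1, a2)`: the symmetric relative difference between
#' two peak-to-peak amplitudes. The mean-denominator makes the predicate
#' symmetric in its two measurements; a reference-based denominator would
#' not be. Two zero amplitudes leave the ratio undefined and raise a
#' measurement error (flat or absent potentials).
#'
#' @param a1,a2 nonnegative amplitudes, microvolt.
#' @return the relative difference as a fraction.
#' @export
#' @examples
#' amplitudeRelativeDifference(1.0, 1.2)  # 0.1818...
amplitudeRelativeDifference <- function(a1, a2) {
  if (a1 < 0 || a2 < 0)
    .sepError("sepsweepInputError", "amplitudes must be >= 0")
  if (a1 == 0 && a2 == 0)
    .measurementError(
      "relative amplitude difference undefined: both amplitudes are zero")
  abs(a1 - a2) / mean(c(a1, a2))
}

#' Are two measurements reproducible?
#'
#' `TRUE` iff the relative amplitude difference is strictly below the
#' amplitude threshold AND the absolute latency difference is strictly
#' below the latency threshold. Measurements must come from the same
#' modality, side and sweep count.
#'
#' @param m1,m2 [SEPMeasurement-class] objects.
#' @param criteria a [ReproducibilityCriteria-class].
#' @return logical scalar.
#' @export
isReproducible <- function(m1, m2, criteria = reproducibilityCriteria()) {
  if (m1@modality != m2@modality || m1@side != m2@side)
    .sepError("sepsweepInputError", sprintf(
      "cannot compare measurements from %s/%s and %s/%s",
      m1@modality, m1@side, m2@modality, m2@side))
  if (m1@sweepCount != m2@sweepCount)
    .sepError("sepsweepInputError", sprintf(
      "cannot compare measurements with different sweep counts (%d vs %d)",
      m1@sweepCount, m2@sweepCount))
  ad <- amplitudeRelativeDifference(m1@amplitudeUV, m2@amplitudeUV)
  ld <- abs(m1@peakLatencyMs - m2@peakLatencyMs)
  ad < criteria@amplitudeFraction && ld < criteria@latencyMs
}

#' Consecutive-pair reproducibility of a measurement series
#'
#' `TRUE` iff every consecutive pair (i, i+1) of the series satisfies
#' [isReproducible()]. Used for the five baseline measurements that
#' establish feasibility before any reduction is attempted; consecutive
#' (rather than all-pairs) comparison matches sequential clinical
#' acquisition.
#'
#' @param measurements ordered list of [SEPMeasurement-class] (length >= 2).
#' @param criteria a [ReproducibilityCriteria-class].
#' @return logical scalar.
#' @export
allConsecutiveReproducible <- function(measurements,
                                       criteria = reproducibilityCriteria()) {
  if (length(measurements) < 2)
    .sepError("sepsweepInputError",
              "need at least 2 measurements to assess reproducibility")
  for (i in seq_len(length(measurements) - 1L)) {
    if (!isReproducible(measurements[[i]], measurements[[i + 1L]], criteria))
      return(FALSE)
  }
  TRUE
}

setMethod("show", "ReproducibilityCriteria", function(object) {
  cat(sprintf(
    "ReproducibilityCriteria: amplitude diff < %.0f%%, latency diff < %g ms\n",
    100 * object@amplitudeFraction, object@latencyMs))
})
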