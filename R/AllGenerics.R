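#' Accessor generics
#'
#' `modality()` and `side()` return the stimulation modality
#' (`"median"` / `"tibial"`) and body side of an object; `sweepCount()`
#' the number of sweeps behind a measurement or averaged potential;
#' `peakLatency()` and `amplitude()` the negative-peak latency (ms) and
#' peak-to-peak amplitude (microvolt) of a measurement.
#'
#' @param x a sepsweep object.
#' @return character, integer or numeric scalar as appropriate.
#' @name accessors
#' @aliases modality side sweepCount peakLatency amplitude
NULL

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("side", function(x) standardGeneric("side"))

#' @rdname accessors
#' @export
setGeneric("sweepCount", function(x) standardGeneric("sweepCount"))

#' @rdname accessors
#' @export
setGeneric("peakLatency", function(x) standardGeneric("peakLatency"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' Acquire one measurement from a source
#'
#' Draws `n` previously unused sweeps from the source, averages them,
#' measures the configured peaks and returns a [SEPMeasurement-class].
#' Successive calls never reuse sweeps; a request beyond the remaining
#' capacity raises a resource error naming the shortfall.
#'
#' @param source an [AcquisitionSource-class].
#' @param n sweep count for this measurement.
#' @return a [SEPMeasurement-class].
#' @export
setGeneric("acquireMeasurement",
  function(source, n) standardGeneric("acquireMeasurement"))

#' @describeIn acquireMeasurement total sweeps drawn from the source so far.
#' @export
setGeneric("sweepsConsumed", function(source) standardGeneric("sweepsConsumed"))

#' @describeIn acquireMeasurement sweeps still available (may be `Inf`).
#' @export
setGeneric("sweepsRemaining",
  function(source) standardGeneric("sweepsRemaining"))
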