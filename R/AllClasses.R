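#' @import methods
#' @importFrom stats rnorm sd fft t.test wilcox.test shapiro.test median
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
NULL

.MODALITIES <- c("median", "tibial")
.SIDES <- c("left", "right")
.POLARITIES <- c("negative", "positive")

## condition helpers -------------------------------------------------------

.sepError <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "sepsweepError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

.formatError      <- function(msg, ...) .sepError("sepFormatError", msg, ...)
.resourceError    <- function(msg, ...) .sepError("sepResourceError", msg, ...)
.feasibilityError <- function(msg, ...) .sepError("sepFeasibilityError", msg, ...)
.measurementError <- function(msg, ...) .sepError("sepMeasurementError", msg, ...)

## SEPTemplate -------------------------------------------------------------

#' Parametric evoked-potential template
#'
#' An `SEPTemplate` describes the noiseless cortical response as a sum of
#' signed Gaussian components. Each component has a label (peak
#' nomenclature: N20, P25 for median-nerve responses; N37, P40 for
#' tibial-nerve responses), a polarity, a center latency, a width (Gaussian
#' sigma) and an amplitude. The compound waveform is the ground truth that
#' the simulator embeds in noise.
#'
#' @slot modality `"median"` or `"tibial"`.
#' @slot components `data.frame` with columns `label`, `polarity`,
#'   `latency_ms`, `width_ms`, `amplitude_uV`, ordered by increasing
#'   latency.
#' @export
setClass("SEPTemplate",
  representation(modality = "character", components = "data.frame"))

setValidity("SEPTemplate", function(object) {
  msgs <- character()
  cmp <- object@components
  need <- c("label", "polarity", "latency_ms", "width_ms", "amplitude_uV")
  if (!(length(object@modality) == 1L && object@modality %in% .MODALITIES))
    msgs <- c(msgs, "modality must be one of 'median', 'tibial'")
  if (!all(need %in% names(cmp)))
    msgs <- c(msgs, paste("components must have columns:",
                          paste(need, collapse = ", ")))
  else if (nrow(cmp) > 0) {
    if (!all(cmp$polarity %in% .POLARITIES))
      msgs <- c(msgs, "component polarity must be 'negative' or 'positive'")
    if (any(diff(cmp$latency_ms) <= 0))
      msgs <- c(msgs, "component latencies must be strictly increasing")
    if (any(cmp$width_ms <= 0)) msgs <- c(msgs, "all widths must be > 0")
    if (any(cmp$amplitude_uV <= 0)) msgs <- c(msgs, "all amplitudes must be > 0")
    labs <- cmp$label
    if (length(object@modality) == 1L && nrow(cmp) >= 2) {
      if (object@modality == "median" && !all(c("N20", "P25") %in% labs))
        msgs <- c(msgs, "median template must contain components 'N20' and 'P25'")
      if (object@modality == "tibial" && !all(c("N37", "P40") %in% labs))
        msgs <- c(msgs, "tibial template must contain components 'N37' and 'P40'")
    }
  }
  if (length(msgs)) msgs else TRUE
})

## NoiseModel --------------------------------------------------------------

#' Band-limited background-noise model
#'
#' White Gaussian noise restricted to the recording band (default
#' 30--500 Hz, the filter setting used for intraoperative SEP acquisition)
#' and rescaled to a target empirical RMS amplitude.
#'
#' @slot bandLowHz,bandHighHz passband edges in Hz.
#' @slot rmsUV target root-mean-square amplitude in microvolt; 0 yields an
#'   identically-zero trace.
#' @slot seed integer seed making the generator a pure function.
#' @export
setClass("NoiseModel",
  representation(bandLowHz = "numeric", bandHighHz = "numeric",
                 rmsUV = "numeric", seed = "integer"))

setValidity("NoiseModel", function(object) {
  msgs <- character()
  if (object@bandLowHz <= 0) msgs <- c(msgs, "bandLowHz must be > 0")
  if (object@bandHighHz <= object@bandLowHz)
    msgs <- c(msgs, "bandHighHz must exceed bandLowHz")
  if (object@rmsUV < 0) msgs <- c(msgs, "rmsUV must be >= 0")
  if (length(msgs)) msgs else TRUE
})

## SimulationConfig --------------------------------------------------------

#' Sweep-simulation configuration
#'
#' Acquisition geometry and sweep-to-sweep variability for the epoch
#' simulator. The epoch must fit inside the inter-stimulus interval
#' (1000 / `stimRateHz` ms; 243.9 ms at the 4.1 Hz stimulation rate).
#'
#' @slot samplingRateHz sampling rate in Hz.
#' @slot epochMs post-stimulus epoch length in ms.
#' @slot stimRateHz stimulation rate in Hz (default 4.1).
#' @slot latencyJitterSdMs SD of the per-sweep common latency shift (ms).
#' @slot amplitudeScaleSdFraction SD of the per-sweep multiplicative
#'   amplitude scale around 1.
#' @slot seed integer master seed; each sweep derives its own substream
#'   from (seed, sweep index).
#' @export
setClass("SimulationConfig",
  representation(samplingRateHz = "numeric", epochMs = "numeric",
                 stimRateHz = "numeric", latencyJitterSdMs = "numeric",
                 amplitudeScaleSdFraction = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@samplingRateHz <= 0) msgs <- c(msgs, "samplingRateHz must be > 0")
  if (object@stimRateHz <= 0) msgs <- c(msgs, "stimRateHz must be > 0")
  if (object@epochMs <= 0) msgs <- c(msgs, "epochMs must be > 0")
  if (object@epochMs > 1000 / object@stimRateHz)
    msgs <- c(msgs, sprintf(
      "epochMs (%.1f) exceeds the inter-stimulus interval (%.1f ms at %.1f Hz)",
      object@epochMs, 1000 / object@stimRateHz, object@stimRateHz))
  if (object@latencyJitterSdMs < 0)
    msgs <- c(msgs, "latencyJitterSdMs must be >= 0")
  if (object@amplitudeScaleSdFraction < 0)
    msgs <- c(msgs, "amplitudeScaleSdFraction must be >= 0")
  if (length(msgs)) msgs else TRUE
})

## SweepSet ----------------------------------------------------------------

#' Collection of single-sweep epochs
#'
#' A `SweepSet` stores un-averaged post-stimulus epochs as a
#' [SummarizedExperiment::SummarizedExperiment]: one `"voltage"` assay
#' (rows = time points, columns = sweeps), the shared time grid in
#' `rowData()$time_ms`, and acquisition metadata (stimulation current,
#' impulse duration, simulation seed) in `metadata()`. Columns are named
#' `sweep_0001`, `sweep_0002`, ... so that `x[, i:j]` selects sweep blocks.
#'
#' @slot modality `"median"` or `"tibial"`.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("SweepSet", contains = "SummarizedExperiment",
  representation(modality = "character", side = "character"))

setValidity("SweepSet", function(object) {
  msgs <- character()
  if (!(length(object@modality) == 1L && object@modality %in% .MODALITIES))
    msgs <- c(msgs, "modality must be 'median' or 'tibial'")
  if (!(length(object@side) == 1L && object@side %in% .SIDES))
    msgs <- c(msgs, "side must be 'left' or 'right'")
  if (!"voltage" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'voltage' is required")
  tm <- SummarizedExperiment::rowData(object)$time_ms
  if (is.null(tm)) {
    msgs <- c(msgs, "rowData must contain 'time_ms'")
  } else if (length(tm) >= 2) {
    dt <- diff(tm)
    if (abs(tm[1]) > 1e-9) msgs <- c(msgs, "time grid must start at 0")
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      msgs <- c(msgs, "time grid must be uniformly spaced")
  }
  if (length(msgs)) msgs else TRUE
})

## AveragedPotential -------------------------------------------------------

#' Averaged evoked potential
#'
#' The sample-wise mean of a block of sweeps; the trace on which peaks are
#' measured. Voltages are stored signed (negative peaks are minima; no
#' negative-up display inversion).
#'
#' @slot modality,side acquisition labels.
#' @slot sweepCount number of sweeps averaged (>= 1).
#' @slot timeMs,voltageUV the trace.
#' @export
setClass("AveragedPotential",
  representation(modality = "character", side = "character",
                 sweepCount = "integer", timeMs = "numeric",
                 voltageUV = "numeric"))

setValidity("AveragedPotential", function(object) {
  msgs <- character()
  if (object@sweepCount < 1L) msgs <- c(msgs, "sweepCount must be >= 1")
  if (length(object@timeMs) != length(object@voltageUV))
    msgs <- c(msgs, "timeMs and voltageUV must have equal length")
  if (length(object@timeMs) >= 2) {
    dt <- diff(object@timeMs)
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
      msgs <- c(msgs, "time grid must be uniformly spaced")
  }
  if (length(msgs)) msgs else TRUE
})

## PeakWindowConfig --------------------------------------------------------

#' Peak search windows
#'
#' Latency windows for the negative and positive cortical peaks. The
#' positive-peak search is additionally constrained to start no earlier
#' than the detected negative peak.
#'
#' @slot negLabel,negLoMs,negHiMs negative peak (N20 / N37) window.
#' @slot posLabel,posLoMs,posHiMs positive peak (P25 / P40) window.
#' @export
setClass("PeakWindowConfig",
  representation(negLabel = "character", negLoMs = "numeric", negHiMs = "numeric",
                 posLabel = "character", posLoMs = "numeric", posHiMs = "numeric"))

setValidity("PeakWindowConfig", function(object) {
  msgs <- character()
  if (object@negLoMs >= object@negHiMs)
    msgs <- c(msgs, "negative window must have lo < hi")
  if (object@posLoMs >= object@posHiMs)
    msgs <- c(msgs, "positive window must have lo < hi")
  if (object@negLoMs >= object@posHiMs)
    msgs <- c(msgs, "negative window must start before the positive window ends")
  if (length(msgs)) msgs else TRUE
})

## SEPMeasurement ----------------------------------------------------------

#' One SEP measurement
#'
#' An averaged potential reduced to the two quantities the reproducibility
#' criterion consumes: the latency of the negative cortical peak (N20 or
#' N37) and the peak-to-peak amplitude to the following positive peak
#' (N20--P25 or N37--P40).
#'
#' @slot modality,side acquisition labels.
#' @slot sweepCount number of sweeps averaged into this measurement.
#' @slot peakLatencyMs latency of the negative peak, ms.
#' @slot amplitudeUV peak-to-peak amplitude, microvolt (>= 0).
#' @slot negVoltageUV,posLatencyMs,posVoltageUV the underlying peak
#'   samples, kept for audit.
#' @export
setClass("SEPMeasurement",
  representation(modality = "character", side = "character",
                 sweepCount = "integer", peakLatencyMs = "numeric",
                 amplitudeUV = "numeric", negVoltageUV = "numeric",
                 posLatencyMs = "numeric", posVoltageUV = "numeric"))

setValidity("SEPMeasurement", function(object) {
  if (object@amplitudeUV < 0) "amplitudeUV must be >= 0" else TRUE
})

## ReproducibilityCriteria -------------------------------------------------

#' Reproducibility thresholds
#'
#' Two measurements are reproducible when their amplitudes differ by less
#' than `amplitudeFraction` (relative to the mean of the two) and their
#' latencies by less than `latencyMs`. Both comparisons are strict
#' ("less than"): boundary-equal differences are not reproducible.
#'
#' @slot amplitudeFraction relative amplitude threshold, default 0.20.
#' @slot latencyMs latency threshold in ms, default 0.5.
#' @export
setClass("ReproducibilityCriteria",
  representation(amplitudeFraction = "numeric", latencyMs = "numeric"))

setValidity("ReproducibilityCriteria", function(object) {
  msgs <- character()
  if (!(object@amplitudeFraction > 0 && object@amplitudeFraction < 1))
    msgs <- c(msgs, "amplitudeFraction must lie in (0, 1)")
  if (object@latencyMs <= 0) msgs <- c(msgs, "latencyMs must be > 0")
  if (length(msgs)) msgs else TRUE
})

## SweepLadder -------------------------------------------------------------

#' Candidate sweep-count ladder
#'
#' The descending candidate counts of the reduction search, plus the rule
#' producing the intermediate (ascent) count tested between two adjacent
#' levels after a failure. Default: 200, 100, 50, 25, 12 with integer
#' midpoints 150, 75, 37, 18 as ascent counts; the reachable terminal set
#' is {12, 18, 25, 37, 50, 75, 100, 150, 200}.
#'
#' @slot counts strictly decreasing candidate counts; the first element is
#'   the baseline count.
#' @slot intermediate `function(upper, lower)` returning the single ascent
#'   count strictly between the two.
#' @export
setClass("SweepLadder",
  representation(counts = "integer", intermediate = "function"))

setValidity("SweepLadder", function(object) {
  msgs <- character()
  k <- object@counts
  if (length(k) < 2) msgs <- c(msgs, "ladder needs at least two counts")
  if (any(diff(k) >= 0)) msgs <- c(msgs, "counts must be strictly decreasing")
  if (any(k < 1)) msgs <- c(msgs, "counts must be >= 1")
  if (length(k) >= 2 && length(msgs) == 0) {
    for (i in seq_len(length(k) - 1L)) {
      m <- object@intermediate(k[i], k[i + 1L])
      if (!(m > k[i + 1L] && m < k[i]))
        msgs <- c(msgs, sprintf(
          "intermediate(%d, %d) = %s does not lie strictly between its levels",
          k[i], k[i + 1L], format(m)))
    }
  }
  if (length(msgs)) msgs else TRUE
})

## AcquisitionSource -------------------------------------------------------

#' Acquisition sources
#'
#' An `AcquisitionSource` abstracts "perform one measurement with n
#' sweeps": every request consumes n previously unused sweeps and returns
#' a fresh [SEPMeasurement-class]. Implementations:
#' `SimulatedSource` (epochs generated on demand from a template + noise
#' model), `SweepSetSource` (backed by a recorded or loaded
#' [SweepSet-class]), and `OracleSource` (a deterministic stub that is
#' reproducible exactly at counts at or above a threshold; used to verify
#' the search state machine).
#'
#' @slot state environment tracking sweeps consumed.
#' @aliases SimulatedSource-class SweepSetSource-class OracleSource-class
#' @export
setClass("AcquisitionSource",
  representation(state = "environment", "VIRTUAL"))

#' @export
setClass("SimulatedSource", contains = "AcquisitionSource",
  representation(template = "SEPTemplate", noise = "NoiseModel",
                 config = "SimulationConfig", windows = "PeakWindowConfig",
                 side = "character", capacity = "numeric",
                 filterAverage = "logical"))

#' @export
setClass("SweepSetSource", contains = "AcquisitionSource",
  representation(sweeps = "SweepSet", windows = "PeakWindowConfig",
                 filterMode = "character", bandLowHz = "numeric",
                 bandHighHz = "numeric"))

#' @export
setClass("OracleSource", contains = "AcquisitionSource",
  representation(threshold = "integer", modality = "character",
                 side = "character"))

## SearchResult ------------------------------------------------------------

#' Outcome of the sweep-count reduction search
#'
#' @slot minimalSweepCount the lowest terminal count with reproducible
#'   potentials.
#' @slot baselineOk whether the five baseline measurements at the baseline
#'   count were consecutively reproducible.
#' @slot trace `data.frame` with one row per tested count in test order:
#'   `count`, `phase` ("baseline", "descent", "ascent"), `reproducible`,
#'   and the two measurements' amplitudes/latencies.
#' @slot reducedBelowBaseline `TRUE` iff the result is below the baseline
#'   count.
#' @slot baselineMeasurements list of the baseline [SEPMeasurement-class]s.
#' @slot finalPrecisionMeasurements list of the three precision
#'   measurements acquired at the minimal count.
#' @slot sweepsConsumed total sweeps drawn from the source.
#' @export
setClass("SearchResult",
  representation(minimalSweepCount = "integer", baselineOk = "logical",
                 trace = "data.frame", reducedBelowBaseline = "logical",
                 baselineMeasurements = "list",
                 finalPrecisionMeasurements = "list",
                 sweepsConsumed = "numeric"))

setValidity("SearchResult", function(object) {
  msgs <- character()
  tr <- object@trace
  if (nrow(tr)) {
    k <- object@minimalSweepCount
    hit <- tr$count == k & tr$reproducible
    if (!any(hit))
      msgs <- c(msgs, "minimalSweepCount must appear in the trace as reproducible")
    below <- tr$count < k
    if (any(below & tr$reproducible))
      msgs <- c(msgs, "no count below minimalSweepCount may be reproducible in the trace")
  }
  if (length(msgs)) msgs else TRUE
})

## SubjectRecord / StudySummary -------------------------------------------

#' Per-subject study record
#'
#' The quantities the study-level statistics consume: the minimal sweep
#' count found for one subject/modality/side, the five baseline
#' peak-to-peak amplitudes measured at the baseline count, and the three
#' amplitudes measured at the minimal count.
#'
#' @slot subjectId identifier.
#' @slot modality,side acquisition labels.
#' @slot minimalSweepCount minimal reproducible count; `NA` if the
#'   baseline itself was not reproducible (algorithm not applicable).
#' @slot baselineAmplitudes numeric(5), microvolt.
#' @slot finalAmplitudes numeric(3), microvolt.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", modality = "character",
                 side = "character", minimalSweepCount = "integer",
                 baselineAmplitudes = "numeric", finalAmplitudes = "numeric"))

setValidity("SubjectRecord", function(object) {
  msgs <- character()
  if (length(object@baselineAmplitudes) != 5L)
    msgs <- c(msgs, "baselineAmplitudes must have length 5")
  if (!is.na(object@minimalSweepCount) && length(object@finalAmplitudes) != 3L)
    msgs <- c(msgs, "finalAmplitudes must have length 3")
  if (length(msgs)) msgs else TRUE
})

#' Study-level summary
#'
#' One row per modality/side group: cohort size, number and proportion of
#' subjects whose sweep count could be reduced below baseline, mean and SD
#' of the minimal counts, mean acquisition time, a one-sample t-test of
#' the minimal counts against the baseline count, a paired Wilcoxon
#' signed-rank test of per-subject precisions (baseline vs minimal count)
#' and a Shapiro-Wilk normality test of the minimal counts.
#'
#' @slot table the summary `data.frame`.
#' @slot baselineCount baseline sweep count the cohort is compared against.
#' @slot stimRateHz stimulation rate used for acquisition times.
#' @export
setClass("StudySummary",
  representation(table = "data.frame", baselineCount = "integer",
                 stimRateHz = "numeric"))

## RunConfig ---------------------------------------------------------------

#' End-to-end run configuration
#'
#' All parameters of a simulate-search-report run in one serializable
#' object (YAML round-trip via [readRunConfig()] / [writeRunConfig()]).
#' Every random operation downstream derives its substream from the single
#' `seed`.
#'
#' @slot modality,side acquisition labels.
#' @slot snr template peak-to-peak amplitude over noise RMS.
#' @slot samplingRateHz,epochMs,stimRateHz acquisition geometry.
#' @slot latencyJitterSdMs,amplitudeScaleSdFraction sweep variability.
#' @slot bandLowHz,bandHighHz recording/noise band, Hz.
#' @slot amplitudeFraction,latencyThresholdMs reproducibility criteria.
#' @slot ladderCounts descending candidate counts.
#' @slot nBaseline baseline measurements (default 5).
#' @slot capacity sweeps available per subject.
#' @slot seed master seed.
#' @export
setClass("RunConfig",
  representation(modality = "character", side = "character", snr = "numeric",
                 samplingRateHz = "numeric", epochMs = "numeric",
                 stimRateHz = "numeric", latencyJitterSdMs = "numeric",
                 amplitudeScaleSdFraction = "numeric",
                 bandLowHz = "numeric", bandHighHz = "numeric",
                 amplitudeFraction = "numeric", latencyThresholdMs = "numeric",
                 ladderCounts = "integer", nBaseline = "integer",
                 capacity = "numeric", seed = "integer"))
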