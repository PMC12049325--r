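## Study-level statistics: measurement precision, acquisition time, and
## the cohort summary with its significance tests.

#' Measurement precision
#'
#' The standard error of repeated peak-to-peak amplitude measurements:
#' sample standard deviation (n-1 denominator) divided by the square root
#' of the number of measurements.
#'
#' @param amplitudes numeric vector of repeated amplitudes (length >= 2).
#' @return numeric scalar (same unit as the amplitudes).
#' @export
#' @examples
#' precision(c(1, 2, 3))  # 1 / sqrt(3) = 0.5774
precision <- function(amplitudes) {
  if (length(amplitudes) < 2)
    .sepError("sepsweepInputError",
              "precision needs at least 2 measurements")
  stats::sd(amplitudes) / sqrt(length(amplitudes))
}

#' Acquisition time of an averaged measurement
#'
#' `sweepCount / stimRateHz` seconds: each sweep occupies one
#' inter-stimulus interval. At the 4.1 Hz stimulation rate, 200 sweeps
#' take 48.8 s. Returned at full precision; reports display it rounded to
#' one decimal.
#'
#' @param sweepCount number of sweeps averaged.
#' @param stimRateHz stimulation rate in Hz (> 0), default 4.1.
#' @return time in seconds.
#' @export
acquisitionTime <- function(sweepCount, stimRateHz = 4.1) {
  if (stimRateHz <= 0)
    .sepError("sepsweepInputError", "stimRateHz must be > 0")
  sweepCount / stimRateHz
}

#' Construct a subject record
#'
#' @param subjectId identifier.
#' @param modality,side acquisition labels.
#' @param minimalSweepCount minimal reproducible count (`NA` if the
#'   baseline was not reproducible).
#' @param baselineAmplitudes the 5 baseline peak-to-peak amplitudes.
#' @param finalAmplitudes the 3 amplitudes at the minimal count.
#' @return a [SubjectRecord-class].
#' @export
subjectRecord <- function(subjectId, modality, side, minimalSweepCount,
                          baselineAmplitudes, finalAmplitudes = numeric()) {
  new("SubjectRecord", subjectId = as.character(subjectId),
      modality = modality, side = side,
      minimalSweepCount = as.integer(minimalSweepCount),
      baselineAmplitudes = baselineAmplitudes,
      finalAmplitudes = finalAmplitudes)
}

#' @describeIn subjectRecord build a record from a completed
#'   [SearchResult-class].
#' @param result a completed [SearchResult-class].
#' @export
asSubjectRecord <- function(result, subjectId) {
  m1 <- result@baselineMeasurements[[1]]
  subjectRecord(
    subjectId, m1@modality, m1@side, result@minimalSweepCount,
    vapply(result@baselineMeasurements, amplitude, numeric(1)),
    vapply(result@finalPrecisionMeasurements, amplitude, numeric(1)))
}

.safeP <- function(expr) {
  tryCatch(suppressWarnings(expr$p.value), error = function(e) NA_real_)
}

#' Summarize a study cohort
#'
#' For each modality/side group: cohort size, how many subjects' sweep
#' counts could be reduced below the baseline count (and the proportion),
#' mean and SD of the minimal counts, mean acquisition time at the
#' stimulation rate, a one-sample t-test of the minimal counts against
#' the baseline count, a paired Wilcoxon signed-rank test comparing each
#' subject's precision at baseline (5 amplitudes) with the precision at
#' the minimal count (3 amplitudes), and a Shapiro-Wilk normality test of
#' the minimal counts. Degenerate groups (e.g. all counts identical) get
#' `NA` p-values and a `degenerate` flag rather than an error. Subjects
#' with `NA` minimal count (infeasible baseline) are counted in `n` but
#' excluded from the tests.
#'
#' @param records list of [SubjectRecord-class] objects.
#' @param baselineCount baseline sweep count, default 200.
#' @param stimRateHz stimulation rate for acquisition times, default 4.1.
#' @param bySide summarize left/right separately (default) in addition to
#'   the per-modality pooled row.
#' @return a [StudySummary-class].
#' @export
summarizeStudy <- function(records, baselineCount = 200L, stimRateHz = 4.1,
                           bySide = TRUE) {
  if (length(records) == 0)
    .sepError("sepsweepInputError", "no subject records supplied")
  df <- do.call(rbind, lapply(records, function(r) data.frame(
    subjectId = r@subjectId, modality = r@modality, side = r@side,
    minimalSweepCount = r@minimalSweepCount,
    baselinePrecision = precision(r@baselineAmplitudes),
    finalPrecision = if (length(r@finalAmplitudes) >= 2)
      precision(r@finalAmplitudes) else NA_real_,
    stringsAsFactors = FALSE)))
  groups <- unique(df[, "modality", drop = FALSE])
  groups$side <- "both"
  if (bySide && length(unique(df$side)) > 1) {
    g2 <- unique(df[, c("modality", "side")])
    groups <- rbind(groups, g2)
  }
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    mod <- groups$modality[i]; sd_ <- groups$side[i]
    sub <- df[df$modality == mod & (sd_ == "both" | df$side == sd_), ]
    k <- sub$minimalSweepCount
    feasible <- !is.na(k)
    kf <- k[feasible]
    if (length(kf) < 3)
      warning(sprintf(
        "group %s/%s has %d feasible subject(s); tests need >= 3",
        mod, sd_, length(kf)))
    nRed <- sum(kf < baselineCount)
    degenerate <- length(unique(kf)) < 2
    data.frame(
      modality = mod, side = sd_, n = nrow(sub), nFeasible = length(kf),
      nReduced = nRed,
      proportionReduced = nRed / nrow(sub),
      meanMinimalCount = mean(kf), sdMinimalCount = stats::sd(kf),
      meanAcquisitionTimeS = mean(acquisitionTime(kf, stimRateHz)),
      tTestP = if (degenerate) NA_real_ else
        .safeP(stats::t.test(kf, mu = baselineCount)),
      wilcoxonP = .safeP(stats::wilcox.test(
        sub$baselinePrecision[feasible], sub$finalPrecision[feasible],
        paired = TRUE)),
      shapiroP = if (degenerate || length(kf) < 3) NA_real_ else
        .safeP(stats::shapiro.test(kf)),
      degenerate = degenerate,
      stringsAsFactors = FALSE)
  })
  new("StudySummary", table = do.call(rbind, rows),
      baselineCount = as.integer(baselineCount), stimRateHz = stimRateHz)
}

#' @describeIn summarizeStudy the summary table as a `data.frame`.
#' @param summary a [StudySummary-class].
#' @export
summaryTable <- function(summary) summary@table

setMethod("show", "StudySummary", function(object) {
  cat(sprintf("StudySummary (baseline %d sweeps, %.1f Hz stimulation)\n",
              object@baselineCount, object@stimRateHz))
  tab <- object@table
  tab$proportionReduced <- sprintf("%.1f%%", 100 * tab$proportionReduced)
  tab$meanAcquisitionTimeS <- sprintf("%.1f", tab$meanAcquisitionTimeS)
  print(tab, row.names = FALSE, digits = 4)
})
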