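# Precision, acquisition time, study summary.

test_that("precision is the standard error of the amplitudes", {
  expect_equal(precision(c(2, 2, 2)), 0)
  expect_equal(precision(c(1, 2, 3)), 1 / sqrt(3))
  # homogeneity: scaling amplitudes by c scales precision by |c|
  x <- c(0.8, 1.1, 1.4, 0.9)
  for (c_ in c(2, -3, 0.5))
    expect_equal(precision(c_ * x), abs(c_) * precision(x))
  # zero for m copies of the same value, any m >= 2
  for (m in c(2, 5, 9)) expect_equal(precision(rep(1.7, m)), 0)
  expect_error(precision(1.0), "at least 2")
})

test_that("acquisition time is sweep count over stimulation rate", {
  expect_equal(round(acquisitionTime(200, 4.1), 1), 48.8)
  expect_equal(round(acquisitionTime(56, 4.1), 1), 13.7)
  expect_equal(round(acquisitionTime(106, 4.1), 1), 25.9)
  expect_equal(acquisitionTime(0, 4.1), 0)
  # linear in sweep count at fixed rate
  expect_equal(acquisitionTime(3 * 50, 4.1), 3 * acquisitionTime(50, 4.1))
  expect_error(acquisitionTime(100, 0), "> 0")
})

makeRecord <- function(id, count, base = c(2, 2.1, 1.9, 2.05, 1.95),
                       fin = c(2, 2.2, 1.8), modality = "median",
                       side = "left") {
  subjectRecord(id, modality, side, count, base, fin)
}

test_that("study summary computes proportions, tests and times", {
  # 15 subjects, 14 reduced below 200
  counts <- c(12, 18, 25, 25, 37, 37, 50, 50, 50, 75, 75, 100, 100, 150, 200)
  set.seed(5)
  recs <- lapply(seq_along(counts), function(i)
    makeRecord(sprintf("s%02d", i), counts[i],
               base = rnorm(5, 2, 0.1), fin = rnorm(3, 2, 0.15)))
  summ <- summarizeStudy(recs)
  tab <- summaryTable(summ)
  expect_equal(tab$proportionReduced[1], 14 / 15)
  expect_equal(tab$nReduced[1], 14)
  expect_equal(tab$meanMinimalCount[1], mean(counts))
  expect_equal(tab$meanAcquisitionTimeS[1], mean(counts / 4.1))
  # minimal counts are well below 200 here
  expect_lt(tab$tTestP[1], 0.05)
  expect_true(is.finite(tab$wilcoxonP[1]))
  expect_true(is.finite(tab$shapiroP[1]))

  # degenerate cohort: all at 200 -> proportion 0, flagged, no crash
  recs200 <- lapply(1:5, function(i) makeRecord(sprintf("d%d", i), 200))
  tab200 <- summaryTable(summarizeStudy(recs200))
  expect_equal(tab200$proportionReduced[1], 0)
  expect_true(tab200$degenerate[1])
  expect_true(is.na(tab200$tTestP[1]))

  expect_error(summarizeStudy(list()), "no subject")
})

test_that("sides are summarized separately when both are present", {
  recs <- c(
    lapply(1:4, function(i) makeRecord(sprintf("l%d", i), 50 + i, side = "left")),
    lapply(1:4, function(i) makeRecord(sprintf("r%d", i), 100 + i, side = "right")))
  tab <- summaryTable(summarizeStudy(recs))
  expect_setequal(tab$side, c("both", "left", "right"))
  expect_equal(tab$meanMinimalCount[tab$side == "left"], mean(51:54))
  expect_equal(tab$meanMinimalCount[tab$side == "right"], mean(101:104))
})

test_that("t-test against baseline has power at the study's effect size", {
  # Monte-Carlo power check: cohorts drawn with true mean 60, SD 50, n = 15
  reps <- 200
  hits <- 0
  set.seed(77)
  for (r in seq_len(reps)) {
    counts <- pmax(1, round(rnorm(15, 60, 50)))
    recs <- lapply(seq_along(counts), function(i)
      makeRecord(sprintf("s%d", i), counts[i]))
    p <- summaryTable(summarizeStudy(recs))$tTestP[1]
    if (!is.na(p) && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
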