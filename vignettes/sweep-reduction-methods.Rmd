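---
title: "Adaptive sweep-count reduction for SEPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sweep-count reduction for SEPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsweep)
```

## The problem

A somatosensory evoked potential is a microvolt-scale cortical response
buried in ongoing EEG that is one to two orders of magnitude larger.
Averaging `n` time-locked post-stimulus sweeps leaves the evoked response
untouched and shrinks the noise by a factor of `1/sqrt(n)`; with the
conventional `n = 200` at a 4.1 Hz stimulation rate one averaged potential
costs `200 / 4.1 = 48.8` s. During surgery that is reaction time lost.
Patients differ widely in their signal-to-noise ratio, so a fixed 200 is
conservative for many of them: the package implements a per-patient search
for the smallest sweep count that still produces *reproducible*
potentials, where reproducibility is the clinical criterion — peak-to-peak
amplitudes within 20 % and peak latencies within 0.5 ms between two
successive measurements.

## The search procedure and its assumptions

The procedure (`findMinimalSweepCount()`) has four stages:

1. **Baseline feasibility** — five measurements at 200 sweeps must be
   consecutively reproducible. We compare *consecutive* pairs rather than
   all pairs: measurements arrive sequentially in the operating room, and
   the criterion itself is defined between two successive measurements.
2. **Descent** — the ladder 200, 100, 50, 25, 12 is walked downward, two
   fresh measurements per count. Two measurements is the minimum that the
   pairwise criterion needs; the count is configurable.
3. **Single ascent** — on the first failure at count `c` with last
   reproducible level `u`, one intermediate count `floor((u + c) / 2)` is
   tested; the result is the intermediate if reproducible there, else
   `u`. A multi-step re-ascent would be possible, but a single midpoint
   test is the simplest rule whose terminal set
   {12, 18, 25, 37, 50, 75, 100, 150, 200} spans the clinically relevant
   range, and the ascent rule is a pluggable function in
   `sweepLadder()`.
4. **Precision** — three more measurements at the minimal count; their
   standard error `sd(amplitudes) / sqrt(3)` is the precision statistic
   compared, per subject, against the precision of the five baseline
   amplitudes (paired Wilcoxon test in `summarizeStudy()`).

Every measurement consumes a *fresh, disjoint* block of sweeps. Reusing
sweeps between the two measurements of a pair would correlate their noise
and spuriously guarantee reproducibility. A measurement in which a peak
cannot be found at all is treated as "not reproducible" — the
conservative reading of a lost potential — while the baseline stage
escalates it to a feasibility error, because a patient without locatable
peaks at 200 sweeps is outside the algorithm's domain.

The state machine is verified exhaustively: against a deterministic
oracle source that is reproducible exactly at counts `>= T`, the search
returns the smallest terminal count `>= T` for every `T` in 1…200
(`test-sweep_search.R`, and criterion 3 of `scripts/acceptance.R`).

## The reproducibility predicate

`amplitudeRelativeDifference()` uses the **mean of the two amplitudes**
as denominator. The clinical criterion says only "difference of less than
20 % between amplitudes"; a reference-based denominator (first
measurement) would make the predicate asymmetric — A reproducible with B
but not vice versa — which we reject. Both comparisons are **strict**:
a latency difference of exactly 0.5 ms fails. The thresholds are plain
slots of `ReproducibilityCriteria`, so sensitivity analyses (e.g. a 10 %
amplitude criterion) are one constructor call away.

## The simulator

No recorded data ship with the package, so every stage is exercised on
synthetic sweeps with known ground truth.

**Templates.** The evoked response is a sum of signed Gaussian bumps —
chosen not for biophysical fidelity but because the compound waveform's
extrema can be located to arbitrary precision by direct evaluation,
giving every peak-measurement test an analytic oracle
(`templatePeaks()`). Defaults: median N20 (negative, 20 ms, sigma 2 ms,
2 µV) + P25 (positive, 25 ms, sigma 2.5 ms, 1.5 µV); tibial N37
(negative, 37 ms, sigma 1.2 ms, 1 µV) + P40 (positive, 40 ms, sigma
1.5 ms, 0.8 µV). Tibial amplitudes are set below median ones, matching
the clinical observation that median responses are larger. The tibial
widths are narrower than the median ones for a geometric reason: two
opposite-polarity Gaussians whose centers are closer than roughly `2 *
sigma` merge into a derivative-like shape whose extrema cannot be less
than about `2 * sigma` apart — with 3 ms between N37 and P40, widths of
1.2–1.5 ms are the realistic upper end.

**Peak calibration.** When opposite-polarity components overlap, each
pulls the other's extremum away from its center (about 0.5 ms for the
median pair). `defaultTemplate()` therefore calibrates the component
*centers* by a fixed-point iteration so that the *observable* compound
peaks sit exactly at the canonical latencies (20/25 ms, 37/40 ms). Ground
truth in all tests is the observable peak, not the component center.

**Noise.** White Gaussian noise is restricted to the 30–500 Hz recording
band by zeroing FFT bins outside the band, then rescaled so its
*empirical* RMS equals the requested value exactly. FFT masking gives
exact band control with no filter transient; the user-facing
`bandpassFilter()` for recorded traces is a conventional zero-phase
4th-order Butterworth instead. SNR is defined as template peak-to-peak
amplitude over noise RMS (`noiseForSNR()`).

**Per-sweep variability.** Each sweep applies a common latency shift
`~ Normal(0, 0.3 ms)` to all components (conduction-time variation moves
the whole complex, not individual peaks) and a multiplicative amplitude
scale `~ Normal(1, 0.10)`. The defaults are plausible clinical
magnitudes; no published per-sweep values exist for these parameters.
Every sweep draws from its own substream derived from
`(seed, sweep index)`, so any subset of a virtual recording is
reproducible and two sources with the same seed are identical.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: 1/f and line-noise components, non-stationary
anesthetic-depth drift, artifacts (no rejection stage exists, matching
the clinical protocol), multichannel montages, and the true waveshape of
cortical SEPs. Conclusions supported here are about the *algorithm* —
its correctness, determinism and SNR behaviour — not about clinical
minimal-count distributions.

## Signal chain choices

* **Filtering placement.** Averaging and linear filtering commute (tested
  to `1e-9` µV), so the simulation-backed source filters the *averaged*
  trace — one `filtfilt` per measurement instead of one per sweep — while
  `SweepSetSource` defaults to per-sweep filtering, the order of a
  clinical acquisition chain. `filterSweepSet()` exposes per-sweep
  filtering directly.
* **Peak detection.** Windowed extremum search (median N20 in
  [15, 28] ms, P25 to 35 ms; tibial N37 in [30, 48] ms, P40 to 55 ms —
  standard clinical ranges, all overridable), preferring interior local
  extrema over window edges, with 3-point parabolic interpolation around
  the extremum. At 5 kHz the raw grid is 0.2 ms; a 0.5 ms criterion needs
  sub-sample latency precision. A constant or monotone window yields an
  edge-flagged result; `measureSep()` converts it into a measurement
  failure. The positive-peak search starts no earlier than the detected
  negative peak, so the amplitude `V(pos) - V(neg)` is nonnegative
  whenever detection succeeds.
* **Acquisition geometry.** 5 kHz sampling (comfortably over twice the
  500 Hz band edge), epochs of 100 ms (median) / 120 ms (tibial), both
  inside the 243.9 ms inter-stimulus interval at 4.1 Hz; 15 mA (median) /
  30 mA (tibial) stimulation current and 200 µs impulses recorded as
  metadata.

## Numerical and degenerate-input choices

* Zero-RMS noise, zero jitter and zero amplitude spread reproduce the
  template exactly; the search then terminates at the ladder minimum with
  precision 0.
* Two zero amplitudes make the relative difference 0/0; this raises a
  measurement error (flat potentials) rather than returning a value, and
  the baseline stage converts it into "algorithm not applicable".
* A signal-free configuration (`snr = 0`) simulates background noise only
  and fails the baseline check — the expected path for a patient without
  potentials.
* Subjects whose baseline is irreproducible are recorded with `NA`
  minimal count; cohort medians censor them at the baseline count 200
  ("needs at least the standard count"), which is conservative and
  preserves monotonicity.
* `t.test`/`shapiro.test` on degenerate cohorts (all counts equal) are
  flagged `NA` instead of erroring.

## Problem sizes

The shipped checks run at the following sizes, chosen to give stable
statistics on a single workstation core: the averaging-law study uses 200
replicates at n = 10/40/160; ground-truth latency recovery 100 replicates
of 200 sweeps; the SNR-monotonicity study 50 simulated subjects at each
of SNR 1.5/3/6 (a full subject consumes roughly 1400–2300 sweeps); the
state-machine verification enumerates all 200 thresholds exhaustively.

## Known limitations

* The terminal ladder values below 50 and the single-ascent rule are a
  reconstruction of clinical practice (the halving ladder and its
  midpoints); both are configurable because devices differ.
* The Gaussian template understates the asymmetry of real SEP complexes;
  absolute amplitude values in simulations should not be read clinically.
* Latency estimates at low SNR are limited by the noise slope at the
  peak, not by the interpolation grid; at SNR 1.5 an appreciable fraction
  of simulated subjects fail the baseline — real cohorts preselected for
  monitorable potentials will fail less often.
* EDF input/output is not implemented; the interchange formats are CSV
  with a JSON metadata sidecar, YAML configurations and JSON results.
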