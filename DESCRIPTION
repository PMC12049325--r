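Package: sepsweep
Title: Adaptive Sweep-Count Reduction for Somatosensory Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the minimal per-patient averaging sweep
    count that still yields reproducible somatosensory evoked potentials
    (SEPs). Implements the descending-ladder search with single-ascent
    recovery over candidate sweep counts, the amplitude/latency
    reproducibility criterion (difference below 20 percent in peak-to-peak
    amplitude and below 0.5 ms in peak latency between consecutive
    measurements), windowed peak detection with parabolic latency
    refinement for the N20/P25 (median nerve) and N37/P40 (tibial nerve)
    cortical components, precision and acquisition-time statistics, and a
    seeded simulator producing single-sweep epochs (Gaussian-component
    evoked templates embedded in 30-500 Hz band-limited EEG noise) so the
    whole pipeline is testable without recorded patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
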