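Package: mscrit
Title: Multiscale Criticality Analysis of Neuronal Avalanches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts neuronal avalanches from multichannel continuous
    recordings (EEG/MEG sensor arrays or any channels-by-samples matrix)
    across a grid of detection thresholds and temporal coarse-graining
    scales, fits the criticality exponents of avalanche size, duration,
    mean-size-per-duration and inter-avalanche-interval distributions by
    truncated discrete power-law maximum likelihood, estimates the
    branching parameter and the kappa deviance measures, and condenses the
    scale dependence of these exponents into a 33-element multiscale
    criticality (MsCr) fingerprint per recording. Includes a
    branching-process generator with ground-truth annotations for
    end-to-end validation, and group-comparison statistics with
    Benjamini-Hochberg false-discovery-rate correction and
    control-referenced z-score deviance fingerprints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
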