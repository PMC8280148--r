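# mscrit — multiscale criticality analysis of neuronal avalanches

`mscrit` characterizes the spatiotemporal structure of multichannel
brain recordings (EEG/MEG sensor arrays, or any channels × samples
matrix) through the statistics of **neuronal avalanches** — clusters of
suprathreshold events spanning channels and consecutive time bins — and
through how those statistics change with the temporal grain of the
analysis. It is aimed at researchers quantifying critical brain dynamics
who need a reproducible, fully tested pipeline from raw signal to a
fixed-length feature vector suitable for group comparison.

## What it computes

At each temporal scale k·Δt (k = 1…10 over a base bin of Δt = 4 ms),
avalanches are extracted across a grid of detection thresholds, and five
criticality parameters are estimated:

| symbol | meaning | estimator |
|---|---|---|
| σ | branching parameter (neural gain) | mean second-bin/first-bin event ratio per avalanche |
| α | avalanche **size** exponent | truncated discrete power-law MLE |
| τ | avalanche **duration** exponent | truncated discrete power-law MLE |
| δ | **inter-avalanche interval** exponent | truncated discrete power-law MLE |
| γ | mean size vs duration scaling | OLS slope of log⟨S⟩ vs log D |

plus three deviance measures of the size distribution: **κ** (deviation
of the empirical CDF from a reference power law at exponent 3/2,
probed at 10 log-spaced points; κ = 1 means power-law agreement),
**generalized κ** (same against the sample's own fitted exponent), and
the **cutoff** (drop-off scale s_c of a x^(−e)·e^(−x/s_c) fit).

Each parameter's scale dependence y(kΔt) is then condensed into the
slope/intercept (a, b) of a fitted line, and likewise for each of the 10
pairwise curves y(x) between parameters — giving the canonical
**33-element MsCr fingerprint** per scale interval (1–5, 3–7, 6–10 Δt):
5×2 single-curve + 10×2 pair-curve + κ, κ_gen, cutoff.

A ground-truth branching-process simulator (Poisson offspring with
tunable branching ratio, Poisson drive, noisy continuous rendering)
validates the whole chain end-to-end, and a statistics module compares
fingerprint tables between groups (t/ANOVA and Mann–Whitney/
Kruskal–Wallis) with Benjamini–Hochberg FDR correction across the 33
features and control-referenced z-score deviance fingerprints.

## Worked example

```r
library(mscrit)

# a slightly subcritical cascade process on a 16-sensor array, rendered
# as a noisy continuous recording at 250 Hz
cfg <- branching_config(n_channels = 16, n_bins = 60000,
                        branching_ratio = 0.9, seed = 1)
sim <- simulate_branching_raster(cfg)
sim
#> <branching_sim> ratio 0.90, 16 channels x 60000 bins: 1183 cascades, 11708 events
rec <- render_continuous(sim$raster, cfg)

# detect events at 3 std, extract avalanches at the base scale
av <- extract_avalanches(detect_events(rec, 3))
av
#> <avalanche_set> 1353 avalanches (k = 1, threshold = 3, 16 channels)
#>   size: median 2 max 161 | duration: median 2 max 55
branching_parameter(av)
#> [1] 0.744

# the full multiscale fingerprint: 3 intervals x 33 named features
fp <- mscr_fingerprint(rec, modality = "eeg", recording_id = "demo")
round(as.data.frame(fp)[, c("a_sigma", "b_sigma", "a_delta",
                            "b_delta", "kappa", "kappa_gen")], 3)
#>   a_sigma b_sigma a_delta b_delta kappa kappa_gen
#> 1   0.053   0.598   0.036   0.913 0.953     0.998
#> 2   0.038   0.678   0.042   0.885 0.964     0.999
#> 3  -0.003   0.975   0.036   0.921 0.984     1.001
```

Reading the output: at the 1–5 Δt interval the branching parameter
rises with scale (a_σ = 0.053 per Δt-multiple) from an intercept of
0.60 — single-bin collisions at fine scales hide part of each cascade,
and coarse-graining recovers it; at this subcritical ratio σ stays
below 1. κ slightly below 1 flags the subcritical deficit of large
avalanches, while κ_gen ≈ 1 says the size distribution's *shape* is
power-law-like once its own exponent is used as reference. Note the
detected σ = 0.744 at k = 1 sits below the generative 0.9: thresholded
rendering merges same-channel coincidences, which is precisely the
scale dependence the multiscale fingerprint is built to expose.

Fingerprint tables from many recordings can be concatenated with
`write_fingerprints()` / `read_fingerprints()` and compared with
`grouped_fingerprints()` + `compare_groups()`.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mscrit simulate --ratio 1.0 --channels 64 --bins 100000 --seed 7 --render --out sim
Rscript inst/cli/mscrit fingerprint sim_recording.tsv --rate 250 --modality eeg --out fp.tsv
Rscript inst/cli/mscrit compare --fingerprints fp.tsv --manifest groups.tsv --control control --q 0.01 --out cmp
```

Inputs can be delimited text matrices (rows = channels) or continuous
EDF files (`read_edf()`).

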