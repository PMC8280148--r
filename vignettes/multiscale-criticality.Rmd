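---
title: "Multiscale criticality analysis with mscrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale criticality analysis with mscrit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscrit)
```

## The model

Cortical population activity, observed through a sensor array (EEG, MEG,
or any channels-by-samples matrix), organizes into *neuronal avalanches*:
bouts of suprathreshold events that cluster in time across channels. In
a system near a critical point, the statistics of these avalanches are
scale free — their sizes, durations and inter-avalanche intervals follow
power laws — and the cascade process is balanced: each event triggers on
average one successor. `mscrit` quantifies this with five parameters per
temporal scale:

* **σ** — the branching parameter, the mean ratio of events in an
  avalanche's second time bin to events in its first. σ = 1 marks the
  critical balance between cascade growth and decay.
* **α, τ, δ** — exponents of truncated discrete power laws fitted by
  maximum likelihood to the avalanche size, duration, and
  inter-avalanche-interval (IAI) distributions.
* **γ** — the slope of log mean size against log duration.

Three deviance measures complete the per-scale profile: **κ** (one plus
the mean difference between a reference power-law CDF at exponent 1.5
and the empirical size CDF at ten log-spaced probe points; κ > 1 means
an excess of large events, κ < 1 a deficit), **generalized κ** (the same
construction against the sample's own fitted exponent, isolating shape
deviance from exponent value), and the **cutoff** (the drop-off scale of
a power-law-with-exponential-tail fit to the sizes).

The *multiscale* step repeats this analysis while the time axis is
coarse-grained by a factor k = 1, …, 10 of the base bin width Δt, and
summarizes each parameter's scale dependence by the slope and intercept
of a least-squares line in k. The **MsCr fingerprint** of a recording
collects, per scale interval (1–5, 3–7 and 6–10 in units of Δt):

* slope and intercept of each of the five parameter curves (10 features),
* slope and intercept of the curve of each of the 10 unordered parameter
  pairs, with the earlier parameter in the canonical order
  σ, α, τ, γ, δ as abscissa (20 features),
* κ, generalized κ and cutoff at the interval's smallest scale (3 features),

for 33 named features per interval (`mscr_feature_names()` fixes the
order). All three intervals are returned; each stands on its own as a
33-feature vector.

## From signal to events

`detect_events()` standardizes each channel to zero mean and unit
standard deviation over the whole recording, so thresholds are in std
units and the result is invariant to per-channel gain and offset. An
*excursion* is a maximal run of samples with |x| above threshold, both
polarities rectified together; exactly one event is registered per
excursion, at the sample of largest |x|. One event per excursion (rather
than one per suprathreshold sample) keeps event counts insensitive to
pulse width; the extremum gives a deterministic time stamp. This is a
convention — continuous data do not dictate an event rule — and it is
the one this package commits to and tests.

Whole-recording standardization (not sliding-window) was chosen for
reproducibility: a single number per channel defines the threshold, and
re-running the analysis cannot depend on window placement. Channels with
zero variance cannot be standardized; they are flagged with a warning
and contribute no events.

Because avalanche statistics are insensitive to the exact threshold in a
sensible range, fingerprints pool avalanches across a threshold grid —
2.5/3.0/3.5 std for EEG, 3.0/3.5/4.0 std for MEG by default. Pooling
concatenates the avalanche samples, which weights each threshold's
empirical distribution by its avalanche count.

`decimate_recording()` brings data to the base rate (250 Hz by default,
so Δt = 4 ms) with an order-8 Butterworth low-pass at 0.8 times the
target Nyquist applied forward and backward (zero phase), followed by
linear interpolation at the new sample times. The rate ratio need not be
an integer. We implemented this directly because the `resample()` of the
signal package miscalibrates amplitude (a constant 2.5 comes back as
2.88 at a 4:1 ratio in version 1.8-1); against an analytically resampled
sinusoid the implementation here is accurate to ~1e-12.

## Coarse-graining and avalanche extraction

`rebin_raster()` merges k consecutive base bins. The binary raster is
combined with a per-channel OR, but avalanche *sizes* at scale k are
computed from the base-resolution event counts carried in
`base_counts`, so no event is lost to the OR: the sum of all avalanche
sizes equals the total event count at every scale (a tested invariant).
A trailing window shorter than k is discarded rather than padded, which
would otherwise create one systematically under-filled bin per record.

An avalanche is a maximal run of consecutive bins with at least one
event on *any* channel, bounded by empty bins or the record edges — no
sensor-adjacency constraint is applied. Size, duration, IAI and the
per-bin event profile are recorded per avalanche.

## Estimator choices

**Branching parameter.** σ averages the second-bin/first-bin event
ratio over avalanches. Duration-1 avalanches contribute a ratio of 0 by
default: the cascade produced no descendants, and for a branching
process with Poisson offspring this makes the estimator unbiased
(E[n₂/n₁] equals the branching ratio). Conditioning on a non-empty
second bin (`include_singletons = FALSE`, also provided) inflates the
estimate by a factor 1/(1 − e^(−m)) when first bins hold single events
— about 1.6 at criticality — so the inclusive form is the default.

**Power-law fits.** `fit_discrete_powerlaw_mle()` maximizes the exact
truncated discrete likelihood on an integer support by 1-D numerical
optimization; there is no xmin search by KS minimization — supports are
fixed by configuration. Defaults (`profile_config()`): sizes on
[1, n_channels × k] (one event per channel per base bin is the nominal
ceiling of the size scaling regime), durations and IAIs on [1, observed
maximum]. Fits with fewer than 50 in-range samples are refused and
flagged rather than returned; all-identical samples signal a divergent
exponent. The estimator is exactly equivariant under sample duplication
and recovers exponents 1.2–2.0 within ±0.01 at n = 10⁴ on true
truncated power laws (tested against a brute-force likelihood grid).

**Cutoff.** The drop-off fit maximizes the joint likelihood of
P(x) ∝ x^(−e)·exp(−x/s_c) over (e, log s_c) on the observed support
[xmin, max(x)]. Bounding the model support by the observed maximum
mirrors the truncated supports used everywhere else and makes the
"pure power law" case well defined: with no interior drop-off the
likelihood increases in s_c, the estimate runs to the upper search
bound (10⁶), and "cutoff beyond the sample maximum" is the reported
signature. The normalization sums the head exactly (up to 5000) and
integrates the smooth tail by the midpoint rule, which keeps the fit
O(1) in the largest avalanche size.

**Degenerate inputs.** Every component of a profile can be missing —
empty rasters, too few avalanches, a single distinct duration — and
missing values propagate into the fingerprint as flagged `NA`s, never
as silent zeros. A fingerprint row always carries all 33 names.

## The synthetic ground-truth generator

`simulate_branching_raster()` realizes the process the σ, α and τ
estimators presuppose: per bin, each active event spawns a
Poisson(branching ratio) number of descendants in the next bin on
uniformly random channels (mean-field, no topology), and fresh cascades
arrive as Poisson(drive) seeds per bin. Events colliding on one
channel-bin merge in the binary raster but remain in the base counts.
Cascade-level size/duration annotations are returned as ground truth. A
runaway guard truncates any cascade whose offspring count exceeds
100 × n_channels, so supercritical runs terminate; truncated cascades
are flagged.

`render_continuous()` turns a raster into a continuous recording: a
3-sample pulse kernel amplitude × (−0.3, 1, −0.3) per event on top of
Gaussian noise. The side lobes keep the excursion rule registering one
extremum per event; with the default amplitude 8, noise 1 and threshold
3, at least 99% of planted events are recovered in the correct bins (a
tested property). What this generator does *not* emulate: oscillatory
background, 1/f spectra, sensor correlations, volume conduction and
non-stationarity of real EEG/MEG. Passing tests therefore validate the
*estimator chain*, not the claim that real recordings are branching
processes.

Default study conditions: 64 channels, branching ratio 1.0, drive 0.02
events/bin, Δt = 4 ms. Two validation studies deviate deliberately and
state why:

* σ-recovery runs use 16 channels, drive 0.01 and 1.3 × 10⁶ bins:
  σ does not depend on channel count, a lower drive minimizes
  contamination of second-bin counts by unrelated seeds (the bias is
  +drive × E[1/n₁]), and the length guarantees ≥10⁴ avalanches.
* critical-exponent runs use the default 64 channels at 5 × 10⁵ bins,
  averaged over six seeds, giving ≈4 × 10⁴ avalanches.

## Fitting the duration exponent: head versus tail

The mean-field critical branching process has avalanche-size exponent
3/2 and duration exponent 2 — but those are *tail* exponents. The exact
duration distribution of a critical Poisson cascade (extinction
probabilities q_{t+1} = exp(q_t − 1)) approaches t^(−2) slowly: the
local log-slope is 1.24 at t = 2, 1.72 at t = 10 and 1.83 at t = 20,
and P(T = 1) = e^(−1) = 0.368 against 0.608 for a normalized t^(−2).
A maximum-likelihood fit from xmin = 1 is dominated by this
pre-asymptotic head and converges to ≈1.61 *in population* — that value
is a property of the distribution, not an estimator error. The size
distribution (a Borel distribution at criticality) converges much
faster, so α is fitted from xmin = 1 without trouble.

Consequently the package's critical-regime validation measures τ with
the fit floor at 10, where the distribution has entered its scaling
regime; this recovers τ ≈ 1.86 on six-seed averages, consistent with
the mean-field tail value given the residual slow convergence. The
default for empirical profiles remains xmin = 1 (configurable via
`profile_config(dur_xmin = )`), since for real recordings the choice of
scaling regime is the analyst's.

## The bin-width rescaling identity

If an exponent-vs-scale curve is linear in absolute scale,
y(KΔt) = aK + b, then re-expressing the base bin width as sΔt gives
y'(k) = a·s·k + b: the slope scales by s and the intercept is
unchanged. This is why a mere change of event *rate* (equivalent to
rescaling Δt) cannot mimic a change in both slopes and intercepts.
`exponent_curves(..., base_k = 2)` implements the re-expression. The
identity is exact only for genuinely linear curves, and most
exponent-vs-scale curves of branching-process data are concave
(log-like saturation), for which slope ratios tend to 1 rather than 2.
The validation therefore gates curves on linearity — R² ≥ 0.95 of the
base-width line over k = 1–10, with |slope| > 0.02 — before asserting
the ratio; on subcritical (ratio 0.9) synthetic runs the qualifying
curves average a slope ratio of ≈2.0 with intercept shifts of a few
percent.

## Group statistics

`per_feature_tests()` applies, per feature, a two-sided t-test /
Mann–Whitney for two groups and one-way ANOVA / Kruskal–Wallis for
more; missing feature values are dropped per feature, and features with
fewer than two usable values in any group (or degenerate, zero-variance
data) are flagged with a missing p-value. `fdr_correct()` runs
Benjamini–Hochberg step-up across the family of one interval's 33
features — missing p-values are excluded from the family size — and the
default reporting level is a conservative corrected q ≤ 0.01.
`deviance_fingerprint()` expresses a target group per feature as
(mean(target) − mean(control)) / sd(control). Cross-interval correction
(3 × 33 tests) is not applied by default; the family is one interval.

## Problem sizes used in validation

The bundled validation (the acceptance script and the test suite) runs
entirely on synthetic data at these sizes, chosen to give
sampling-error bands comfortably inside the asserted tolerances:
MLE recovery at n = 10⁴ × 50 seeds; σ recovery on ≥10⁴ avalanches per
ratio; critical exponents on six 500k-bin, 64-channel runs; κ
calibration at n = 10⁵ × 20 seeds; the rescaling identity on four
60k-bin renderings; null calibration of the statistics on 1000
replicated 12-vs-12 comparisons.

## Known limitations

* The event rule (one event per excursion, rectified amplitudes) and
  the σ estimator are conventions; both are configurable, and results
  should be compared within, not across, conventions.
* κ_gen here is "κ against the self-fit exponent". Other definitions
  exist in the literature; treat absolute κ_gen values as
  package-specific.
* Whether κ should consume event-count sizes or summed-amplitude
  "magnitudes" is ambiguous in the field; this package uses
  event-count sizes throughout.
* No spatial-scale iteration (sensor subsampling) and no artifact
  preprocessing: inputs are assumed cleaned.
* The EDF reader covers continuous recordings with one common sampling
  rate; EDF+D (discontinuous) files and annotation channels are not
  supported.

## A minimal session

```{r example, eval = FALSE}
cfg <- branching_config(n_channels = 16, n_bins = 60000,
                        branching_ratio = 0.9, seed = 1)
sim <- simulate_branching_raster(cfg)
rec <- render_continuous(sim$raster, cfg)
fp  <- mscr_fingerprint(rec, modality = "eeg", recording_id = "demo")
fp[, c("interval", "a_sigma", "b_sigma", "kappa")]
```
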