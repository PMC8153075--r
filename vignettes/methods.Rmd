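---
title: "Methods: synthetic Ternus experiments and their eye-metric analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic Ternus experiments and their eye-metric analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternuseye)
```

`ternuseye` studies the crossmodal freezing effect — the bias of Ternus
apparent motion toward "group motion" when brief sounds accompany the
visual frames — through three eye metrics (gaze duration, microsaccade
rate, pupil size) and the psychometric report. This vignette explains the
models behind each stage, the tunable parameters and their defaults, the
numerical decisions, and what the synthetic data generator does and does
not emulate.

## Experiment designs

Every trial presents two 30-ms Ternus frames separated by an ISI drawn from
{50, 80, 110, 140, 170, 200, 230} ms, so SOA = ISI + 30 ∈ {80..260} ms. On
sound trials, beeps are synchronous with the frame onsets. A pre-trial
central fixation lasts 3–5 s (uniform, rounded to the 2-ms sample grid);
the response probe appears 300 ms after the second frame's offset.

Four variants are built by `build_design()`: E1 randomizes everything
(24 trials per SOA × sound cell, directions balanced 12/12, 336 trials in
2 blocks); E2 blocks the sound factor (4 × 84 trials, two all-sound and two
no-sound blocks in seeded counterbalanced order); E3 blocks SOA; E4 is the
localization control — the same timeline with no displayed frames. The
source description of E3 is arithmetically ambiguous ("blocks of 168
trials" vs "12 consecutive trials per SOA level"); we default to 7
fixed-SOA blocks of 24 trials (168 total, sound × direction counterbalanced
within block), with 168-trial blocks selectable via `e3_block_trials`.

## The synthetic-data generator

The generator's purpose is to produce data with exactly the statistical
structure the analysis assumes, so that every downstream stage has a ground
truth. It is a pure function of `(params, seed)`.

**Behavior.** Group-motion reports are Bernoulli draws with
$p = \mathrm{logistic}((\mathrm{SOA}-\mathrm{PSE}_c)/s_c)$,
$s_c = \mathrm{JND}_c/\ln 3$. Defaults are the pooled condition means of
the experiments the package emulates: PSE 180.1 ms (baseline) / 100.2 ms
(sound), JND 37.9 / 42.6 ms. Control-experiment reaction times are normal
(SD 100 ms) truncated at 150 ms with means 603 / 537 ms.

**Gaze traces** (500 Hz) are fixational drift plus microsaccades. Drift is
AR(1) per axis (coefficient 0.99, innovation SD 0.003°), chosen so the
median-based velocity threshold lands near 4–5 °/s — well below injected
peak velocities, which keeps the detector's sub-threshold rise time inside
one sample period. Microsaccade onsets come from an inhomogeneous point
process: base rate 1.5 events/s (typical of fixation data) multiplied by a
stimulus-locked gain locked to each frame. The gain is a piecewise-smooth
well (cosine ramps): after a 100-ms latency the rate drops by `depth`
(0.70 baseline, 0.90 sound), stays suppressed for `duration` (350 ms
baseline, 600 ms sound), then recovers into a 40% rebound overshoot. Sound
therefore deepens and prolongs the inhibition, which is what makes the late
(750–1000 ms) sound-minus-baseline rate difference negative. A 20-ms
minimum gap between events is enforced; because a refractory gap biases the
realized rate below the nominal one, event candidates are drawn with the
renewal-corrected hazard $h(t)=\lambda(t)/(1-\lambda(t)\,\bar d)$, where
$\bar d$ is the mean event duration plus the gap — with this correction a
nominal homogeneous 1.5 Hz process realizes 1.5 events/s.

Each event's amplitude is lognormal (median 0.5°, sdlog 0.35, giving the
sub-1.5° range typical of microsaccades); peak velocity is
`main_seq_slope` (100 s⁻¹) × amplitude × lognormal noise (sdlog 0.12) —
the main sequence. The waveform is a minimum-jerk displacement ramp, for
which duration follows analytically as $D = 1.875\,A/V_{peak}$ (clamped to
6–80 ms and rounded to the grid); its direction is near-horizontal
(±15° about 0 or 180°), with the sign drawn to pull the eye back toward
the fixation point so the position stays bounded.

**Pupil.** Each stimulus event adds a gamma-shaped impulse response
$h(t) = (t/t_{max})^{n} e^{n(1-t/t_{max})}$ with shape $n = 10.1$ and
time-to-peak $t_{max} = 930$ ms (the standard pupillary response kernel);
displayed frames contribute 60 a.u., beeps an extra 40 a.u. on sound
trials, on a 3000-a.u. base level with per-trial wander (SD 30 a.u.) and
AR(1) measurement noise (SD 8 a.u.). Blinks are a Poisson process
(0.05 s⁻¹, duration 150 ± 30 ms, floor 60 ms) that sets gaze and pupil to
missing.

**Subject heterogeneity.** A per-subject effect-strength scalar
(N(1, 0.3), truncated at 0) jointly scales the sound-induced PSE shift and
the sound-induced extra inhibition, plus independent jitter on baseline PSE
(SD 12 ms) and JNDs (SD 4 ms). The joint scaling is what couples the
oculomotor and behavioral effects across participants, giving the
delta-rate vs delta-report correlation its negative sign; its magnitude is
not calibrated to any particular participant sample.

**What the generator does not emulate:** saccade curvature and dynamic
overshoot, drift with persistent direction (it is mean-reverting noise),
binocular disparities, pupil foreshortening artifacts, session-long
fatigue or learning trends, and response omissions. Passing tests
demonstrate the pipeline's correctness on data satisfying its assumptions,
not robustness to every artifact of real recordings.

## Microsaccade detection

Velocity is estimated with the 5-sample moving-window estimator
$v_n = (x_{n+2}+x_{n+1}-x_{n-1}-x_{n-2})/(6\Delta t)$ — exact for linear
signals, noise-suppressing otherwise; the first/last two samples are
invalid, and samples adjacent to blink gaps propagate missingness. The
detection threshold is $\lambda \sigma_x$ with $\lambda = 8$ and
$\sigma_x = \sqrt{\mathrm{median}(v^2) - \mathrm{median}(v)^2}$ computed
over all horizontal velocities of a session pooled (the per-session
convention). Sessions with $\sigma_x < 10^{-6}$ °/s are flagged degenerate
and refuse detection rather than returning nonsense.

The criterion uses the horizontal component only, as stated in the source
description; a conventional 2-D elliptic criterion is available via
`detection_params(criterion = "elliptic")`. Candidates are maximal
supra-threshold runs of at least ⌈3 ms / Δt⌉ = 2 samples, with half-open
extents (duration = n·Δt). Filters run in a single left-to-right pass:
durations outside [3, 110] ms are dropped, then any event whose onset is
closer than 20 ms to the previous *kept* event's offset (keep-earlier
tie-break). Offset-to-onset is the stricter reading of the interval rule;
onset-to-onset is selectable. Amplitude is measured between the mean
positions of the 2 samples before onset and 2 after offset; peak velocity
is the maximal 2-D speed inside the event; events at trace edges are
computed from available samples and flagged.

## Rate curves and segments

Onsets (not full event extents) enter a trials × bins raster on the 2-ms
grid; counting onsets makes event mass exactly conserved under the
unit-sum kernel. The raw rate is the column mean times the sampling rate —
"normalized by the number of trials and the sampling rate" is read as
divide-by-trials, multiply-by-samples/s, which yields events/s (the
alternative, divide by both, has no rate dimension). Smoothing uses the
causal kernel ω(τ) = α²τe^(−ατ) with α = 1/20 ms⁻¹, discretized from lag
0, truncated at 200 ms (10 time constants; a support below 5/α is
rejected) and renormalized to unit sum. Convolution is left-zero-padded,
so an event contributes no rate before its onset; mass overhanging the
window's right edge is truncated. The default epoch is [−500, 1000) ms
around the lock event; segment means use half-open bins S1–S4 =
[0,250), [250,500), [500,750), [750,1000) ms.

## Pupillometry

Blink samples (pupil missing or ≤ 0, padded ±50 ms, overlapping pads
merged) are linearly interpolated between the flanking valid samples;
leading/trailing gaps take the nearest valid value; valid samples are
never altered. The session's interpolated samples are z-scored ("variance
normalization" read as division by the SD), trials are epoched to the
first frame, and the mean over the half-open [−100, 0) ms baseline — 50
samples, excluding the frame-onset sample — is subtracted. Averages are
two-level: trials → participant, then participants with equal weight, with
SE across participants, matching across-participant error reporting.

## Psychometric fitting

The two-parameter logistic is fitted by maximum likelihood as a binomial
GLM with logit link; location μ = −β₀/β₁ and scale s = 1/β₁. IRLS with the
GLM's standard starting values is deterministic given the data, which is
the property the fit contract requires. Likelihood-based fitting (rather
than least squares on proportions) is well-defined at 0/1 proportions; no
lapse or guess parameters are included. Degenerate inputs — identical
proportions at every level, all 0s or all 1s, or a non-positive fitted
slope — yield `converged = FALSE` and no estimates instead of garbage
numbers. A PSE outside the tested SOA range is reported and flagged
`extrapolated`, never clipped, since near-edge PSEs are meaningful in this
paradigm. JND = s·ln 3 agrees with numerical inversion of the fitted curve
at 25%/75% to 10⁻⁸ (tested).

## Cluster-based permutation statistics

For paired participant × time matrices, the pointwise paired t series is
thresholded at the two-tailed t critical value at the test's α (df = n−1);
runs of contiguous supra-threshold samples of one sign form clusters scored
by summed t (maxsum). The null distribution is the maximum absolute
cluster mass over random per-participant sign flips of the paired
differences — exact exchangeability under the paired null — with p =
(1 + #{null ≥ |mass|})/(N + 1), which cannot be zero. Both the
cluster-forming threshold and the maxsum statistic are the cited method's
defaults; the source names only the method, its 1000 iterations and
α = 0.05. Zero-variance time points get t = 0 with a warning rather than
±∞. The implementation is vectorized (a sign matrix times the difference
matrix; per-trial sums of squares are sign-invariant), so the
200-dataset × 1000-iteration null calibration runs in well under a minute.

`null_cluster_fwer()` verifies familywise error control empirically:
two conditions per participant drawn i.i.d. from the identical process
(kernel-smoothed rates of homogeneous 1.5-Hz Bernoulli rasters, 24 trials,
17 participants) across 200 datasets.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: full 336-trial designs;
6 virtual participants for the default end-to-end dataset; 2000 trials for
the detection round-trip (≥ 90% of injected events recovered with onset
error ≤ 1 sample); 10,000 1-s trials for the homogeneous-rate check
(±0.05 events/s); 10,000 trials per SOA level for PSE recovery; 200 null
datasets × 1000 sign-flip iterations for error-rate calibration, compared
against α plus two Monte-Carlo standard errors. Exact identities (kernel
unit mass, baseline-window zero mean, z-score moments, JND closed form)
are asserted at 10⁻⁸–10⁻¹²; statistical quantities at 2–3 standard errors
of their sampling distribution under fixed seeds.

## Known limitations

- The gaze-duration distribution is bounded by the simulated recording
  window ([−800, 1600) ms around the first frame), so absolute durations
  are not comparable to free-viewing values; condition contrasts are.
- The per-session σ is computed over concatenated trials; sessions mixing
  grossly different noise regimes would need per-block statistics.
- The horizontal-only criterion misses near-vertical saccades by design
  (the generator makes them rare, as in typical fixation data); use the
  elliptic criterion when vertical components matter.
- Whether the source analysis thresholded the vertical component, and
  whether its 20-ms interval rule was onset- or offset-referenced, is not
  stated; both choices are configurable and the defaults are the stricter
  readings.
- The permutation test assumes exchangeability of the paired differences
  across the sign flip, i.e. no condition-order confound within
  participant.
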