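---
title: "Methods: simulated wearable streams, repetition scoring, and trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated wearable streams, repetition scoring, and trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telerehab)
```

## The system in one paragraph

telerehab models the software chain of a wearable remote rehabilitation
training system for stroke patients. A patient wears two 9-axis IMU
modules (upper/lower arm or thigh/calf) or a data glove (one IMU plus
five flex sensors), sampled at 30 Hz, and follows a standard training
video. The software filters the streams, re-expresses them relative to
the pose at movement onset ("headless mode"), cuts them into
repetitions, summarizes each repetition by five motion features, and
compares the feature vector to the standard movement's template. A
repetition whose weighted similarity meets the difficulty threshold
(40/60/80% for easy/moderate/hard) is a *valid action* and scores one
game point. A companion module implements the trial-design arithmetic
used to evaluate such a system clinically: noninferiority sample size,
stratified block randomization, the Fugl-Meyer assessment (FMA) data
model, and confidence intervals and comparisons recomputed from group
summaries.

Because no patient-level sensor data are available, the package ships a
first-class synthetic-stream generator with ground-truth labels; every
downstream stage is tested against those labels.

## Synthetic streams: what they emulate and what they do not

`generate_session()` produces repetition-structured streams with a
closed-form movement profile: by default a raised cosine
$p(t) = \tfrac{A}{2}\,(1 - \cos 2\pi\tau)$, $\tau \in [0,1)$ over the
repetition, so the peak-to-trough span equals the amplitude parameter
$A$ exactly, and optionally an out-and-back minimum-jerk quintic.
Repetitions are separated by rest pauses; Gaussian noise of standard
deviation `noise_sd` is added per channel; `smoothness < 1` injects
4–8 Hz tremor harmonics scaled by $(1-\text{smoothness})$, emulating
the jerk inflation of impaired movement. For limb exercises the profile
rides on the accelerometer's movement axis over a 1 g gravity baseline;
for hand exercises it is encoded as a wrist pitch angle (degrees) in the
gravity direction, and the glove flex channels mirror the normalized
profile scaled into [0, 1].

Defaults were chosen once as a plausible rehabilitation bout: 10
repetitions of 2 s separated by 1 s pauses, amplitude 2 (g for limb
movements; hand examples use 45 degrees), noise SD 0.02, full
smoothness. All randomness flows from one explicit seed per call, so
equal parameters give bit-identical streams; `degrade_repetitions()`
exploits this by regenerating the stream with selected per-repetition
amplitudes rescaled, leaving the noise realization untouched.

The generator is a stand-in, not a reconstruction: it does not model
limb biomechanics, magnetometer disturbances, sensor drift, or the
actual standard-video waveforms. Passing tests therefore demonstrate
that the pipeline recovers what the generator encodes (counts,
amplitudes, smoothness ordering, rotation invariance), not that it
generalizes to clinical recordings.

## Preprocessing

**Sliding filter.** `sliding_filter()` is a centered moving average
(default window 5 frames, about 0.17 s at 30 Hz — the minimal reading of
"sliding filtering"). At the edges the window truncates to the available
samples, so output length equals input length and constants are fixed
points. The filter attenuates a 2 s raised-cosine peak by about 0.5%,
which is why amplitude-recovery checks use a 1% tolerance.

**Headless-mode rebasing.** `rebase_orientation()` builds an orthonormal
basis from each device's first-sample accelerometer (gravity) and
magnetometer vectors (a TRIAD construction) and maps all vector channels
through its transpose. A stream already in the canonical z-up pose is
unchanged; a stream pre-rotated by any fixed mounting rotation $R$
rebases to the same result, because the estimated basis rotates with the
data. The first *sample* (not an averaged rest pose) defines the basis,
matching the convention that the pose at the start of each movement is
the origin. If the first-sample magnetometer is parallel to gravity the
heading is undefined and an arbitrary horizontal reference is used; the
rotation-invariance guarantee then degrades to pitch/roll only.

**Segmentation.** The delimitation of repetitions is not specified by
the system description, so the package uses hysteresis thresholding on
the filtered primary channel: candidate segments are maximal runs above
a low threshold (40% of `threshold_frac` times the signal range above
the 5th-percentile baseline), kept if they rise past 70% of
`threshold_frac`, then extended outward to the 1%-of-range crossing so
boundaries track movement onset. Segments shorter than `min_duration`
(0.5 s) are dropped. The two-level design keeps detection robust when a
repetition's peak sits near `threshold_frac` itself (e.g. a repetition
degraded to 30% of nominal amplitude with the default
`threshold_frac = 0.3`). Ground-truth-driven tests justify the
algorithm: on noiseless default streams boundaries land within ±3
frames of truth, and counts are exact up to noise of 5% of amplitude.

**Primary channel.** The scalar feature formulas need one channel per
exercise. Limb exercises use the magnitude of dynamic acceleration
(Euclidean distance from the first-sample accelerometer vector, in g);
hand exercises use the wrist pitch angle derived from the glove
accelerometer. Both are invariant to mounting orientation after
rebasing, which the tests assert to 1e-6 relative tolerance.

## Motion features

Per repetition, on the primary channel $x_1,\dots,x_N$ at $f_s = 30$ Hz:

| Feature | Definition | Meaning |
|---|---|---|
| AMP | $\max x - \min x$ | movement magnitude |
| MEAN | $\bar x$ | movement direction |
| RMS | $\sqrt{\overline{x^2}}$ | dynamic energy |
| JERK | $\dfrac{\frac{1}{N-1}\sum_i ((x_{i+1}-x_i)f_s)^2}{f_s^2\,\mathrm{AMP}^2}$ | smoothness (lower = smoother) |
| Strength | mean flex deflection from the first frame | exercise effort (glove only) |

The JERK normalization divides by $f_s^2\,\mathrm{AMP}^2$ to make the
metric dimensionless and invariant to amplitude rescaling
($J(kx)=J(x)$); it is defined as 0 for constant signals. Strength
excludes the reference frame from the time average (so a constant
deflection of 0.5 scores exactly 0.5) and is clipped at 0; for streams
without a glove it is reported as unavailable rather than raising an
error, and scoring renormalizes the remaining weights. Every feature is
checked against an independent brute-force loop implementation to 1e-12
relative tolerance, and the power-mean inequality RMS ≥ |MEAN| is
property-tested.

## Similarity scoring and game logic

Per-feature similarity uses a relative-error kernel,
$s = \max(0,\, 1 - |f - r|/|r|)$ clipped to [0, 1] (absolute scale 1
when $r = 0$); the description states only that closer-to-standard means
higher score, so this is the simplest kernel with that monotonicity.
`combined_score()` is the convex combination over the template's active
feature set. Hard mode uses all five features with weights
(0.5, 0.2, 0.1, 0.1, 0.1) in the order (AMP, MEAN, RMS, JERK,
Strength); easy ("simple") mode uses AMP alone. No moderate-mode
feature set is documented, so the package interpolates with
{AMP, RMS} at weights (0.7, 0.3) — configurable per template, like
everything else in `reference_template()`. Exercises other than the
Bobath handshake reuse the same weight vectors, since only that one
worked mode is documented.

Validity is the inclusive comparison `score >= threshold` with
thresholds 0.40/0.60/0.80 (the description gives percentages without
strictness; ties count as valid). Each valid action adds one point
(`points_per_action = 1` — one apple picked); the session score is the
percentage of valid repetitions, and 0 for an empty session.

## Prescription and adaptation

The catalog holds the 16 exercises (8 upper-extremity, 5 hand, 3
lower-extremity) with their required device sets. Initial difficulty is
banded on the enrollment FMA total — [0, 33] easy, [34, 66] moderate,
[67, 100] hard. The cut points are a package design decision (no
published mapping exists): the 0–100 scale is split into three equal
bands, and they are configurable. Adaptation follows the once-daily
rule: at most one adjustment per calendar date; a session-score change
of 5 points or less (on the 0–100 scale) requires no adjustment; larger
changes step the difficulty exactly one level, capped at the extremes.
Single-level stepping is the conservative reading of prescription
updates; repetition counts and session minutes remain manual fields for
the prescribing physician.

## Trial-design computations

**Sample size.** For a noninferiority comparison of two means with
margin $\delta = 0.40\sigma$:
$$n = \left\lceil \frac{(z_{\alpha/2}+z_\beta)^2\, 2\sigma^2}{(|\mu_1-\mu_2|+\delta)^2} \right\rceil$$
With $z_{\alpha/2}=1.96$ (one-sided $\alpha=.025$), $z_\beta=0.84$
(80% power), $\mu_1=11.0$, $\mu_2=10.0$, $\sigma=5.5$: $n = 47$ per
group, and $\lceil 47/(1-0.20)\rceil = 59$ after 20% dropout
inflation. Monotonicities (non-increasing in margin and effect,
non-decreasing in $\sigma$ at fixed absolute margin) are
property-tested.

**Confidence intervals.** `group_ci()` uses Student's t with $n-1$
degrees of freedom on (n, mean, SD) summaries; this choice reproduces
the published group CIs to the printed 2 decimals, whereas a
normal-quantile interval does not. Report output rounds to 2 decimals;
internal computation is full precision.

**Two-sample tests.** `two_sample_test()` computes Welch's
unequal-variance t test from summaries by default, with the pooled
variant available; both reproduce the published total-change comparison
(p = .005) at 3 decimals. The Welch p-value is cross-checked in the
tests against numeric integration of the t density.

**Proportions.** `compare_proportions()` reports the 2×2 chi-square
test (Yates-corrected by default; the uncorrected Pearson value matches
the published adverse-event comparison p = .27), Fisher's exact test,
and incidence percentages, flagging the exact test when any expected
cell is below 5.

**Randomization.** `block_randomize()` performs stratified permuted-block
randomization, default block length 4 (set but not published; any even
length works): within each stratum (study center) every complete block
contains each arm exactly `block_length/2` times in seeded-random
order, so complete strata are exactly 1:1 and no prefix imbalance
exceeds half a block. One seed makes the whole allocation list
reproducible.

**FMA model.** `fma_assessment()` validates 50 items (33 upper, 17
lower) each in {0, 1, 2} and `fma_totals()` returns subtotals and
total, with maxima 66/34/100 forced by the item partition.

## Numerical choices and degenerate inputs

- Segmentation of a flat (or empty-activity) stream returns an empty
  list, never an error; scoring an empty stream returns session score 0.
- `feature_jerk` defines $J=0$ at AMP = 0 (constant signal).
- `feature_similarity` falls back to an absolute scale of 1 unit when
  the reference is 0, keeping the kernel defined for MEAN references of
  either sign.
- Repetition indices are 0-based half-open over the frame list in all
  segment and ground-truth structures; R-side slicing converts
  explicitly.
- Degrading with `factor = 0` flattens a repetition (AMP ≈ 0); factor 1
  is excluded so a degraded repetition is always intentionally invalid.
- Randomization truncates the final incomplete block, which is the
  standard permuted-block behavior when a stratum size is not a
  multiple of the block length.

## Problem sizes used in the checks

The shipped tests and the reproduction script run on desk-scale inputs
chosen to exercise every code path quickly: streams of 2–10 repetitions
(a few hundred frames at 30 Hz), 120-case randomization lists, and
random property sweeps of 10–30 cases per invariant. The summary
statistics are recomputed from the published group summaries (n = 54/55
per arm, counts over 60 per arm), which are inputs, not simulations.

## Known limitations

- Synthetic kinematics are one-axis profiles with additive noise;
  multi-joint coupling, compensatory trunk movement, and sensor drift
  are out of scope, so template similarity here is easier than on real
  patients.
- Sensor fusion is deliberately minimal (no Kalman/Madgwick attitude
  estimation); rebasing relies on the first sample being a usable rest
  pose.
- The moderate-mode feature set and the FMA-to-difficulty bands are
  package conventions, configurable but not validated against the
  clinical deployment.
- Patient-level clinical outcomes cannot be reproduced from published
  group summaries; the statistics module recomputes exactly the
  summary-derived quantities (CIs, tests, proportions) and no more.
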