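---
title: "Multimodal wrist-band verification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal wrist-band verification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristauth)
```

## The verification problem

A wearable wrist band measures two biometric signals: a single-lead ECG
(the user touches an outer electrode with the opposite index finger,
closing a circuit across the chest) and a multispectral skin photomatrix
(MSP) — the pattern of visible and infrared light diffusely reflected
from the wrist tissue, whose spatial structure reflects the anatomy
under the band and is stable within a person.  `wristauth` implements
the complete processing, matching and evaluation chain for this setting:
feature extraction from both raw streams, distance-based matching
against an enrolled template, optional user-template guided filtering of
the probe, per-modality max normalization so one shared threshold drives
both classifiers, majority-voting fusion, and a leave-two-records-in
verification protocol with FAR/FRR/EER reporting.

## Feature pipelines

**ECG.** The continuous 250 Hz stream is baseline-corrected with a
zero-phase 0.5–40 Hz Butterworth band-pass (two biquad sections run
forward and backward; a 60 Hz notch is available for hardware without
its own power-line stage).  R-peaks are found with a Pan-Tompkins
detector: 5–15 Hz band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive signal/noise thresholds with a
200 ms refractory period and RR search-back.  Each beat yields a
160-sample P-QRS-T fragment spanning 67 samples before to 92 after the
R-peak (0.64 s).  The first 36 pulses are pair-averaged into 18, then
grouped in order into **6 records of 3 averaged pulses**.

**MSP.** One acquisition cycle drives 16 LEDs (8 visible + 8 infrared)
in sequence while 32 photodiodes integrate; a cycle is a 16 × 32
intensity matrix.  Readings are averaged over the 8 sources of each
type (mean rather than sum, so the feature scale is independent of the
LED count), giving 32 visible + 32 infrared values per cycle and mode.
Red/IR cycle *i* is paired with yellow/IR cycle *i* in acquisition
order and concatenated as `[32 red | 32 yellow | 32 red-run IR |
32 yellow-run IR]` — the block order is a package constant so distances
are well defined.  18 of the 20 per-mode cycles are selected uniformly
at random (seeded) and grouped into **6 records of 3 features**,
mirroring the ECG record structure.

## Matching, normalization and fusion

A template is the mean of the six vectors from two enrollment records
(N = 6); a probe is the mean of one record's three vectors (M = 3).
The match score is the plain Euclidean distance ‖t − s‖₂.  (The squared
form is available via `squared = TRUE`; the two differ after
normalization and the package follows the evaluation convention of the
un-squared norm.)

Raw ECG and MSP distances live on incomparable scales (different
dimensionality and units).  Each modality's pooled distances are
divided by their maximum, pinning both maxima to exactly 1, after which
a *single shared threshold* `th` drives both classifiers: accept iff
the normalized distance ≤ `th` (ties accept, keeping the FAR/FRR step
functions right-continuous).  Decisions fuse by majority voting,
`g1 + g2 > α`: with two modalities α = 1 is the AND rule and α = 0 the
OR rule.  In evaluation mode the normalization constants are the pooled
per-run maxima; the CLI's deployment path instead freezes constants
from a calibration pool and stores them with the template.

The acceptance inequality is distance-like (smaller is better): FAR is
non-decreasing and FRR non-increasing in the threshold, and the
monotonicity is asserted on every curve the package produces.

## The user-template guided filter

`guided_filter_1d()` performs a local affine fit of the *guide* signal
to the input in every moving window of half-width `r`:
`a = cov(g, x) / (var(g) + eps)`, `b = mean(x) − a·mean(g)`, with the
output averaging `a·g + b` over all windows covering a sample.  In
verification the guide is the enrolled template and the input the
incoming probe — the template itself is never filtered.  For MSP the
filter runs per 32-detector block (cuts at 32/64/96) so the fit never
spans heterogeneous source types; windows truncate at block and vector
ends using the in-bounds statistics.

Two numerical choices matter:

* **`radius = 4`** (9-sample windows) preserves the sharp transitions
  that carry identity in MSP profiles; much larger windows smear the
  QRS complex of a filtered probe relative to its unfiltered template.
* **`eps_rel = 3e-4`** (so `eps = 3e-4·range(guide)²`).  An earlier
  default of `0.01` proved harmful on this pipeline's inputs: because
  probes are already 3-pulse/3-cycle averages, their noise is small,
  and an `eps` comparable to the windowed variance of mid-amplitude
  structure (P and T waves, MSP transitions) shrinks those waves toward
  window means — biasing genuine probes *away* from their own template
  and degrading every guided-filter condition.  With `eps` well below
  the variance of real structure, the fit is essentially exact wherever
  the template has shape and still averages noise out of flat
  stretches.  Both values are arguments to `gf_params()`.

Filtering helps exactly when genuine probes carry removable noise
(additive, high-frequency) and hurts when an imposter's difference from
the template is locally affine (pure gain), which the fit can absorb.
This trade-off is inherent to the method and is visible in the
evaluation: the filter's benefit concentrates at the strict zero-FAR
operating point, where it rescues noisy genuine records.

## Verification protocol and metrics

For each subject, each of the C(6,2) = 15 enrollment combinations
builds a template; the subject's other four records are genuine probes
and every other subject's records *at the same four held-out indices*
are imposter probes (keeping genuine/imposter record counts
symmetric — the protocol description does not pin down which imposter
records to use).  An n-subject cohort therefore yields n·15·4 genuine
and n·15·4·(n−1) imposter trials.  Distances are normalized per
modality over the entire pooled run, and each guided-filter condition
is a self-contained run with its own normalization constants.

The threshold grid is every distinct observed normalized distance plus
0 and 1, so the step functions are evaluated exactly.  EER is the value
where FAR meets FRR (linear interpolation between the bracketing grid
points when the step functions cross between them); PD.1 is 100 − FRR
at the largest threshold with FAR ≤ 1%; FRR0 is FRR at the largest
threshold with FAR = 0.  Metrics are computed on the globally pooled
trial set, not averaged per subject.

## The synthetic cohort: what it emulates, and what it does not

No subject data ships with the package; `simulate_cohort()` is the
stated world in which everything is tested.  Its defaults were chosen
once, to land the default 150-subject cohort in a realistic,
non-degenerate regime — single-modality EERs in the low single digits
with fused EER below both — and are not tuned per test.

* **ECG**: each beat is five Gaussian waves (P, Q, R, S, T; Q and S
  negative) at physiological timings, RR = 0.8 s (snapped to the
  sample grid so noise-free subjects give bit-identical pulses),
  baseline wander at 0.3 Hz, white noise (sd 0.03 vs R = 1), and a
  per-beat log-normal gain following an AR(1) with lag-1 correlation
  0.9 — electrode contact quality drifts slowly, so beats of one
  record share most of their gain.  With 3% per-beat probability a
  *muscle-tremor episode* starts: four beats receive > 20 Hz noise at
  5× the baseline sd.  Such EMG-like bursts sit above the QRS
  detector's band (detection survives) but inside the 0.5–40 Hz
  feature band, so the affected records land far from their own
  template.
* **MSP**: each subject's 128-D base pattern is, per block, a mean
  level modulated on the log scale by a low-order Fourier series plus
  two narrow Gaussian bumps at random detector positions.  The bumps
  give identity a sharp, local component: a purely smooth
  (locally-affine) identity would be fitted away by the guided filter,
  which is neither realistic nor consistent with the abrupt
  transitions real wrist anatomy produces.  Intra-subject variability
  combines i.i.d. reading noise (gain 4%, additive 0.01), a per-cycle
  shared gain (sd 0.06; contact pressure and LED drive do not average
  out across sources), 4%-probability motion cycles with correlated
  detector noise, and an edge-contact model: detectors 1–4 and 29–32
  of each block are attenuated by a per-cycle severity (mean 0.15).
  Setting `contact_sd > 0` and `detach_prob > 0` emulates the
  integrated band whose edge contact varies between cycles; the
  defaults model the firmly attached separate sensor.
* **Identity placement**: between-subject dispersion (scale 0.12)
  acts mainly on wave timing/width (ECG) and pattern shape (MSP),
  with amplitudes secondary.  This matters for the guided-filter
  conditions: timing and sharp-shape differences survive a local
  affine fit, amplitude differences do not.

The episodic artifact structure is what makes the world *FRR-limited*:
most genuine trials are easy, a few are catastrophic, and imposters
stay well separated.  In that regime OR fusion (rescue a failed
modality with the other) beats AND fusion on EER while AND remains
stronger at fixed low FAR — the qualitative pattern the evaluation
module's acceptance checks assert across five cohort seeds.

The generator does **not** model heart-rate-dependent morphology
(T-wave changes with exercise), arrhythmia, template aging across
days, optical photon transport, or ambient-light leakage.  A green
test therefore establishes that the pipeline, matching rule, fusion
logic and metrics behave correctly in a plausible world — not that the
hardware's published error rates are reproduced; those were measured
on a 150-subject human cohort that is not publicly available.

## Degenerate inputs and numerical notes

* Signals shorter than 2 s, cohorts with fewer than 2 subjects, pulse
  counts below 36, wrong cycle/source counts, and all-zero distance
  pools raise errors rather than degrading silently.
* Peaks whose 160-sample window would cross a signal boundary are
  skipped; more than 36 detected pulses use the first 36.
* Zero-phase filtering uses odd-reflection padding (3 s); assertions
  about "DC removed" hold after the filter transient, and noise-free
  genuine distances are ~10⁻³ of imposter distances rather than exact
  zeros for the same reason.
* The guided filter's box sums use a single vectorized cumulative sum;
  agreement with an explicit per-window brute-force implementation is
  asserted to 10⁻¹⁰ across lengths 16–160.
* All randomness flows from one master seed through per-subject
  derived streams, so subject *i* is identical in any cohort of size
  ≥ *i* with the same seed, and the MSP 18-of-20 selection is applied
  per subject from a seeded stream (the protocol's only stochastic
  step).

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(30, seed = 1)
records <- process_cohort(cohort)

pool <- run_protocol(records, gf = "none")
glance(pool)

curve <- far_frr_curve(pool, "fused_or")
compute_eer(curve)
compute_pd_at_far(curve, 1)
compute_frr_at_zero_far(curve)
autoplot(curve)

evaluate_cohort(records, gf = c("none", "both")) |> tidy()
```

## Known limitations

* The evaluation's trial pool is quadratic in the cohort size; a
  150-subject run holds ~1.35 M trials in memory (tens of MB) and a
  guided-filter condition costs about a minute of CPU.
* Deployment-mode normalization (frozen constants) is exposed through
  the CLI but the package's statistical guarantees are all stated for
  evaluation-mode (per-run pooled) normalization.
* Weighted (score-level) fusion and identification-mode (1:N) metrics
  are out of scope; the fusion is strictly decision-level with equal
  votes.
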