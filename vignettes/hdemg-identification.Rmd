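---
title: "Identifying task and effort level from HD-EMG activation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying task and effort level from HD-EMG activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdemgid)
```

## The problem

Myoelectric interfaces for people with incomplete spinal cord injury must
recognize which movement a user intends — and ideally how forcefully —
from surface EMG alone. Injury reorganizes motor-unit recruitment, so the
*spatial* distribution of muscle activity over a high-density electrode
grid carries subject-specific information that a single bipolar channel
cannot see. `hdemgid` implements a complete identification pipeline for
isometric forearm tasks (elbow flexion/extension, forearm
supination/pronation) at graded effort (10, 30, 50 %MVC), recorded with
three electrode arrays over five muscles (240 monopolar channels at
2048 Hz) together with joint torque.

The package asks, on fully synthetic data with known ground truth, the
questions a practitioner would ask of such a pipeline: does adding a
spatial feature to the map intensity help? and which features survive
muscle fatigue and slow electrode changes?

## The model and its features

Signals are screened per channel for artifacts (relative power below
12 Hz, relative power at the line frequency and its first four harmonics,
and total power bounds), band-pass filtered 15–350 Hz (4th-order
Butterworth, applied forward–backward so the phase is zero and the
effective magnitude response is squared), and cleaned of the first six
power-line harmonics by an adaptive least-mean-squares canceller
(discussed below). On non-overlapping 250 ms windows, each muscle's
electrode region is summarized by its *activation map*

$$HM_{i,j} = \mathrm{RMS}(sEMG_{i,j}),$$

from which three feature definitions derive, always concatenated over the
five muscles:

* **I** — map intensity, $I = \log_{10}\frac{1}{N}\sum_{i,j} HM_{i,j}$.
  The log respects the nonlinear growth of EMG amplitude with force.
* **I+CG** — intensity plus the map's center of gravity
  $CG = \sum HM_{i,j}\,(i,j)^\top / \sum HM_{i,j}$ in 1-based
  electrode-pitch units (15 features). CG is invariant to a global gain,
  which is exactly why it resists amplitude drift.
* **Diff** — the conventional bipolar benchmark: the log RMS of the
  difference of two consecutive channels along the fiber direction
  (region's central column, middle row by default; configurable since the
  original electrode choice follows placement recommendations rather than
  a formula).

Classification is linear discriminant analysis (pooled within-class
covariance with a small ridge `lambda = 1e-6`, uniform priors, ties broken
by class order), evaluated in 1000 iterations of random *balanced* 50/50
train/validation splits. Per class, one-vs-rest counts give accuracy,
sensitivity, precision (undefined when a class is never predicted — such
entries are excluded from averages) and specificity; indices are computed
per iteration and then averaged.

Epochs enter the classifier only when the measured torque cooperates: a
window qualifies if its mean torque stays within ±5 %MVC of a 10 %MVC
target or ±10 %MVC of a 30/50 %MVC target, and the 20 windows closest to
the target (absolute deviation of the window mean; ties to the earlier
window) are kept per contraction. "Closest" is our operationalization —
the source protocol states the band and the count but not the distance.
Sixty no-activity epochs come from the 3 s rest prefixes, ranked by lowest
mean absolute torque (the original selection rule among the 144 candidate
rest windows is unstated; a seeded random mode exists as an alternative).

Three experiment drivers compose these pieces:

* `run_short_term()` — train and validate within the submaximal set,
  either 5 classes (4 tasks + rest) or 13 (task × level + rest; rest is
  subsampled to the per-class count, another unstated detail we fixed by
  choice), with a per-effort-level tally of the mixed-level classifier.
* `run_time_effect()` — train on half the submaximal epochs (levels
  mixed), validate once on held-out 50 %MVC epochs from the same part of
  the session (condition A) and once on the first 20 % TDC of endurance
  contractions recorded later (condition B).
* `run_fatigue()` — split each endurance contraction into five equal-count
  TDC segments, train on the first, validate on all five with equal class
  counts.

Statistical comparisons use the paired t-test on per-iteration indices and
a mixed repeated-measures ANOVA (one within factor, one between factor)
with Mauchly's sphericity test; when Mauchly rejects at 0.05 the reported
degrees of freedom are Greenhouse–Geisser adjusted. Both the adjusted and
unadjusted p-values are always returned. One caution a user should know:
the folklore that the GG-adjusted p-value is never smaller than the
unadjusted one is only true where it matters, in the rejection region
(F ≳ 1); for F well below 1, shrinking both degrees of freedom can lower
the p-value. The adjustment is about test size, not a pointwise ordering.

## The synthetic session generator

No public HD-EMG dataset matches this recording protocol, so the package
ships a generator (`sim_config()`, `simulate_session()`) whose defaults
*are* the study conditions: 240 channels in three grids (6×16 forearm
array split 5/6/5 columns over anconeus, brachioradialis and pronator
teres — the true channel-to-muscle split is not recoverable, so it is a
configurable convention — plus two 6×12 upper-arm arrays), 2048 Hz, 3 s
rest + 10 s submaximal contractions at the three target levels in random
order, and endurance contractions at 50 %MVC (60 s by default; the
original "until failure" duration is subject-specific).

Each muscle is driven by one band-limited (15–350 Hz) Gaussian source
projected through a 2-D Gaussian spatial profile whose center and gain
depend on the (muscle, task) pair; effort scales gains as
$g \propto \mathrm{level}^{0.7}$, a concave law consistent with the
nonlinear EMG–force relation. Channels add independent noise (20 µV RMS),
a common power-line component with per-channel coupling, and the torque
trace wanders slowly around its target well inside the selection band.
Sources are normalized by the band-pass filter's *theoretical* white-noise
gain rather than each realization's sample SD: per-realization
normalization would pin the summed windowed power of a recording and
anti-correlate its analysis windows, biasing split-based evaluation below
chance on null data.

Endurance recordings add two slow disturbances with separate knobs:
*fatigue drift* — per-muscle gain growth (differential across muscles, as
prime movers fatigue hardest) and compression of the source band toward
low frequencies, implemented by crossfading progressively low-passed
copies of the source so the windowed median frequency falls monotonically
along the contraction; and *gel drift* — a per-channel multiplicative
log-gain random walk emulating gel drying.

Six small presets (84 channels at 1024 Hz, shorter contractions) build the
diagnostic fixtures used throughout the tests: `separable`,
`spatial_only` (identical regional intensity by construction, distinct
source centers — intensity features are provably uninformative),
`chance` (task labels independent of the signals), `fatigue_drift`,
`gel_drift`, and `artifact_channels`. What the generator does *not*
emulate: motor-unit action potentials, volume conduction, crosstalk
between muscles, or non-Gaussian interference — so passing properties here
show the pipeline recovers the structure this model encodes, not that a
patient study would reach any particular accuracy.

## Numerical choices and edge cases

* Log features clamp their argument at `eps = 1e-6` mV (rest windows can
  be near-silent); an all-zero map has no CG — callers substitute the grid
  centroid with a warning.
* Artifact map cells are repaired in the intensity domain (not the raw
  signals) by an exact thin-plate-spline scattered-data interpolant over
  the good cells; it reproduces planar fields exactly and is our stand-in
  for triangulation-based interpolation, with a nearest-neighbour
  fallback outside the convex hull of good cells (edge channels — the
  source method is silent there).
* The line canceller is offline and two-pass: an adaptation pass over the
  whole signal with a step decaying as $1/(1+t/T_0)$ (fast acquisition
  while gradient noise anneals away), then a processing pass from the
  converged weights with a small tracking step (1e-5). Subtracting six
  estimated harmonic pairs from $n$ samples of pure noise necessarily
  perturbs the signal by about $\sqrt{12/n}$ RMS — under 2 % for
  recordings of 30 s and longer.
* TDC segments split contraction windows into equal counts, remainder to
  the last segment; epoch windows are aligned to sample 0 so maps,
  torque summaries and Diff windows describe identical spans.
* Balanced splits make priors uniform; `lambda` guards rank-deficient
  pooled covariances (e.g. duplicated channels).
* All randomness (generator, splits, subsampling) derives from explicit
  integer seeds; identical configuration and seed reproduce results
  bit-for-bit.

## Problem sizes used in the shipped checks

The packaged tests run the full 240-channel, 2048 Hz epoch bookkeeping on
a complete submaximal session, and the behavioural properties (spatial
information, fatigue, gel drift) on the 84-channel presets with 100–200
evaluation iterations — sizes we chose so the whole suite documents the
pipeline quickly while still exercising every code path at the real
montage's scale where counts matter. `scripts/acceptance.R` regenerates
the bookkeeping quantities from scratch at the full scale for any seed.

## Known limitations

* LDA is the only classifier, by design — the object of study is the
  feature sets, and frequency-domain features are out of scope.
* The CG is a coarse spatial summary; classes that differ only in
  higher-order spatial structure (same centroid) would defeat it.
* The generator's fatigue model changes gain and bandwidth but not, e.g.,
  conduction-velocity-induced shape changes of single potentials.
* Bundles store float32; saving quantizes fresh float64 signals (loading
  and re-saving is lossless).
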