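---
title: "Phase-space screening of localized ECG features: models and methods"
author: "psrcvd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-space screening of localized ECG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrcvd)
```

## The method in one paragraph

Cardiovascular abnormality perturbs specific, localized parts of the ECG
beat: the PR interval (atrial conduction), the QRS complex (ventricular
depolarization) and the QT interval (depolarization plus repolarization).
`psrcvd` screens a single-lead record by delineating each beat, slicing out
those three features, delay-embedding sliding windows of consecutive
feature segments into 2-D phase portraits, counting the pixels the
trajectory touches (black boxes, $n_b$), and tracking the coefficient of
variation $CV = \sigma/\mu$ of those box counts in a second sliding window.
A regular rhythm traces clean, heavily overlapping loops with a stable box
count; a chaotic rhythm spreads its trajectories, and the box counts both
rise and fluctuate. A per-feature two-threshold rule
($CV \le Th_{final\_max}$: healthy; $CV \ge Th_{final\_min}$: unhealthy;
between: tending to unhealthy) turns the trend into a three-class decision.

## Pipeline stages and their parameters

| Stage | Parameters (defaults, units) | Notes |
|---|---|---|
| Band-limiting | high-pass 1 Hz, low-pass 40 Hz, order 4 | cascaded Butterworth, forward-backward (zero phase) so fiducials do not shift; record ends mirror-padded by $2 f_s / f_{hp}$ samples so the high-pass settling transient falls outside the data |
| Normalization | none | $E_n(t) = (E(t) - E_{min})/(E_{max} - E_{min})$ per record; required by the unit-square rasterizer |
| Delineation | Haar levels 3 and 5; refractory 200 ms | see below |
| Interval windows | $W_1 = 20$ segments, step 1 | 109 consecutive intervals give 90 windows |
| Embedding | delay 20 ms ($= \mathrm{round}(delay \cdot f_s/1000)$ samples) | 5 ms collapses the portrait onto the diagonal, 35 ms overstretches it |
| Rasterization | $N = 100$, mode `line` | exact supercover tracing of the polyline; cells $[i/N, (i+1)/N)$, closed at 1 |
| Trend | stats window $w = 20$ counts, step 1 | $\mu$, $\sigma$ (population moment), $CV = \sigma/\mu$; $k$ counts give $k - 19$ values |
| Decision | published or learned `threshold_pair` per feature | cohort aggregation: max of patient maxima / min of patient minima |

Two deliberately different standard deviations coexist: the *trend* uses
the population second central moment (divide by $w$), because it describes
the dispersion of the specific window at hand; the *inferential* layer
(confidence intervals, paired $t$, repeated-measures ANOVA) uses the sample
SD (divide by $n-1$).

## Beat delineation

Both boundary detection and feature extraction run on an orthonormal Haar
multiresolution decomposition: level-3 detail coefficients (8 ms scale at
1 kHz) carry QRS energy; the level-5 scale (32 ms) matches P and T waves.
Implementation choices, in order of application:

* **R peaks** are local maxima of the smoothed level-3 detail envelope
  above $0.3\times$ its rolling 2-s RMS, with a 200 ms refractory period.
  Secondary peaks below 35% of the upper-quartile peak envelope (T waves,
  edge transients) are rejected, and each surviving peak is refined to the
  signal's local extremum. All thresholds are relative, so detection is
  invariant to positive rescaling of the input.
* **QRS onset/offset**: walking outward from the R peak, the boundary is
  the first sample whose adjacent 12 ms are quiet *on average*, where
  "quiet" means the smoothed derivative is below
  $\max(3\%\ \mathrm{of\ the\ QRS\ derivative\ peak},\ 1.5\times$ the
  median derivative in a $\pm 150$ ms window$)$; the boundary is then
  refined to the pointwise threshold crossing, bounded by the run length
  so noise cannot drag it away. The noise floor term keeps the criterion
  attainable on noisy records; a fixed 10% threshold without it
  systematically under-segments smooth complexes by over 10 ms.
* **P onset** is the 5% upward crossing (relative to the left-of-apex
  baseline) of the largest level-5-scale-smoothed positive bump in a
  220–40 ms window before QRS onset.
* **T offset** uses the tangent method — the tangent through the point of
  steepest descent after the T apex, intersected with the local baseline —
  *extended by the apex-to-steepest-point distance*. For a smooth
  (Gaussian-flank) T wave the plain tangent intersection lands about one
  flank-width short of the true end of the wave; the extension is exact for
  Gaussian flanks and keeps recovered QT durations within a few
  milliseconds on clean records.

Delineation windows that reach past the record ends are clipped rather
than dropping the beat; a beat is dropped (with a warning) only when the
clipped window leaves delineation infeasible or the fiducial ordering
$P_{on} < QRS_{on} < R < QRS_{off} < T_{off}$ fails.

On zero-jitter synthetic records the recovered durations err by at most
~10 ms (QRS) and ~5 ms (PR, QT); the test suite enforces a 15 ms median
bound and 90% of PR intervals within ±15 ms.

## Rasterization and its oracle

"Pixels the trajectory passes through" is implemented as exact supercover
line tracing: for each segment of the embedded polyline the parameter
values at every gridline crossing are enumerated, and the (piecewise
constant) cell index is evaluated at each crossing and at each midpoint
between crossings. The test suite checks this against an independent
brute-force oracle that intersects every pixel's closed-form parameter
intervals per axis, for grids up to $16 \times 16$. A `point` mode (only
pixels containing sample points) exists for sensitivity checks; `line`
counts dominate it by construction.

The grid resolution $N = 100$ over the unit square is a design default —
fine enough that a healthy window fills roughly 5–10% of the cells, coarse
enough that counts are stable; none of the package's statistical
conclusions depend on a specific $N$, and it is configurable everywhere.

## What the synthetic generator emulates

`generate_record()` builds each beat from Gaussian bumps (P, Q, R, S, T)
whose $\pm 3\sigma$ extents realize the requested PR/QRS/QT/RR durations,
so fiducial ground truth is known analytically. Defaults: 1 kHz sampling,
healthy beats (PR 160, QRS 90, QT 380, RR 800 ms) with 2% log-normal
beat-to-beat jitter on durations and amplitudes.

The unhealthy block is *paroxysmal*: a quiescent run (half the block,
capped at 20 beats) of regular beats with abnormal intervals (e.g. QT
520 ms for the long-QT regime), followed by an active episode in which

* a three-level severity staircase (runs of 7 beats) applies *signed*
  morphology displacements — ST elevation/depression, a Q/S-depth seesaw,
  P-wave inversion — plus interval prolongation and amplitude modulation;
* 30% of beats are polymorphic ectopics (broad P-less QRS, raised R,
  compensatory pause), each drawn with its own morphology;
* duration/amplitude jitter is inflated to 6%.

This structure was chosen deliberately. Box counts are unions of
overlapping trajectories, and a union saturates: under *any* statistically
stationary regime — however large its jitter — the window-to-window count
dispersion, and hence the CV, settles to nearly the healthy level. What
keeps real diseased rhythm's CV elevated is non-stationarity and
polymorphism (paroxysmal episodes, ectopy, ST drift), and those are the
ingredients the generator reproduces. The *signed* displacements matter
for the same reason: scaling a loop nests it inside its larger neighbours
(the union degenerates to a rolling maximum), whereas displacements that
sweep through zero occupy disjoint pixel regions.

What the generator does **not** emulate: clinically validated arrhythmia
electrophysiology, 12-lead geometry, intracardiac electrogram morphology,
electrode artifacts, or muscle noise beyond white Gaussian noise and
sinusoidal (0.3 Hz) baseline wander. Tests passing on these fixtures show
the pipeline's internal consistency and its ability to recover planted
contrasts; they do not certify clinical performance on real records.

## Threshold learning and the study conditions

Training traces are annotated with `a` (last all-healthy stats window) and
`b` (first all-unhealthy stats window), derived from the ground-truth beat
labels pushed through both windowing stages: stats window $m$ draws on
beats $m \dots m + W_1 + w - 2$. Per patient, $Th_{max,i}$ is the CV
maximum over windows $1 \dots a$ and $Th_{min,i}$ the minimum over
$b \dots$ end; the cohort thresholds are the max of the maxima and the min
of the minima. Healthy-only records contribute their whole trace to the
healthy side — without them the healthy threshold is a maximum over short
prefixes and underestimates the full-trace extremes of unseen healthy
records. A learned pair with $Th_{final\_max} \ge Th_{final\_min}$ is
flagged degenerate; `classify_cv()` refuses it, while `classify_trace()`
degrades to a two-class midpoint rule with a warning.

The end-to-end recovery experiment (test suite and acceptance script) uses
20 healthy records (45 beats) and 20 transition records (45 healthy + 39
unhealthy beats) — 39 because at $W_1 = w = 20$ it is the span of exactly
one all-unhealthy stats window, which then straddles the full
quiescent-to-active count swing. Thresholds are learned on a stratified
80% split; the held-out records are classified subject-level (unhealthy if
any window crosses $Th_{final\_min}$). The expected outcome under these
conditions is zero false positives and full sensitivity, with learned
thresholds qualitatively matching the published pattern: a low healthy
band well separated from the unhealthy band.

Subject-level aggregation (any window unhealthy → subject unhealthy, else
any tending → tending, else healthy) is a design choice; the three-band
rule itself is applied per window. The tending band is read as the open
interval between the two thresholds, with both boundary comparisons
inclusive on their own side.

## Evaluation layer

`diagnosis_measures()` computes the nine standard diagnostic ratios from
confusion counts, as percentages, reporting a measure with a zero
denominator as `NA` rather than 0. FNR is computed as $FN/(FN+TP)$, i.e.
$100 - Se$. `mean_ci()`, `paired_t_one_tailed()` (right-tailed, on
unhealthy − healthy differences) and `rm_anova_two_conditions()` (two
within-subject conditions, $F$ on df $(1, n-1)$, equal to the squared
paired $t$ — an identity the tests verify numerically) cover the
inferential summaries; `critical_value()` exposes the upper-tail $t$ and
$F$ quantiles (1.669 and 3.991 at $\alpha = 0.05$ for a 65-subject
cohort).

## Numerical and degenerate-input conventions

* Sample indices are 1-based; feature slices are half-open
  `[start, end)`, so the QRS segment is a byte-for-byte prefix of the QT
  segment.
* The Haar transform crops to the largest multiple of $2^{levels}$;
  level-5-scale smoothing is a 32-sample centered moving average (Haar
  approximations proper are block-constant and would quantize onsets to
  32 ms).
* A stats window of all-zero counts records $CV = 0$ with a warning.
* Constant signals refuse normalization ("degenerate normalization");
  flat records detect zero beats; an empty synthetic record (0 + 0 beats)
  is valid and empty.
* Ties in the decision rule: $CV \le Th_{final\_max}$ is healthy and
  $CV \ge Th_{final\_min}$ is unhealthy — both inclusive.
* All randomness flows through explicit integer seeds; generation restores
  the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run synthetic records of 10–130
beats and cohorts of 40 records (about 3,500 beats end to end), sizes at
which the full pipeline — delineation, ~50 portraits per record at
$N = 100$, trend and classification — completes in well under a minute on
one core while still exercising every windowing identity at the method's
native $W_1 = w = 20$.

## Known limitations

* The delineator assumes upright R and T waves on the analysis lead and a
  discernible P bump for PR measurement; inverted-T or P-absent rhythms
  yield erratic PR/QT segments (which the classifier reads, correctly, as
  abnormal variability, but the recovered durations are not meaningful).
* Thresholds learned on one generator configuration (or one cohort) do not
  transfer to another scale of record; the published values shipped in
  `published_thresholds()` came from a real 65-patient cohort and are only
  meaningful for records with comparable CV scale.
* Box counting is single-resolution by design; no fractal-dimension
  estimate across grid sizes is attempted.
* The WFDB reader supports the common format-16 single-segment layout
  only.
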