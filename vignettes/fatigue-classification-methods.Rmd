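---
title: "Classifying running fatigue from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying running fatigue from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Blood lactate accumulation is the reference marker of fatigue in endurance
training, but measuring it requires repeated finger-prick samples — unusable
during everyday running. Surface electromyography (sEMG) is non-invasive and
wearable, and muscle fatigue leaves signatures in the sEMG signal: spectral
compression (median-frequency decline), amplitude growth, and altered
activation timing. `fatiguecps` implements a pipeline that learns to map
sEMG features onto fatigue *phases* derived from the lactate curve of an
incremental treadmill test:

* **class 1 (aerobic)** — lactate production and clearance in balance,
* **class 2 (anaerobic)** — lactate accumulating, from the lactate
  threshold to the maximum accumulation at exhaustion,
* **class 3 (recovery)** — after exhaustion, lactate clearing.

The phase boundaries are found by change-point segmentation (CPS) of the
sparse lactate series, and a random forest is trained to predict the phase
of each sEMG burst from its features.

## Signal model and preprocessing

sEMG is sampled at 1926 Hz from up to ten channels: vastus lateralis (VL),
vastus medialis (VM), biceps femoris (BF), semitendinosus (SM) and
gastrocnemius (GM) of both legs. Each channel is band-limited with
zero-phase Butterworth filters: an order-10 high-pass at 20 Hz (motion
artifacts, baseline wander) and an order-10 low-pass at 400 Hz (electronic
noise). Two numerical choices deserve note:

* **Zero-phase application.** Activation *timing* is a feature downstream,
  so the filters are applied forward-backward. This doubles the effective
  stopband attenuation and removes group delay.
* **Second-order sections.** The order-10 high-pass at 20 Hz / 1926 Hz has
  poles of modulus ~0.99; in expanded transfer-function form, coefficient
  rounding floors the achievable attenuation near -60 dB. The design is
  therefore implemented as a cascade of biquads (analog Butterworth
  prototype, bilinear transform), which reaches the analytic response to
  well below -100 dB. `filter_response_db()` reports the analytic
  single-pass magnitude response; the nominal "60 dB at 450 Hz" sometimes
  quoted for an order-10/400 Hz low-pass is not attainable by any
  Butterworth of that order (~10 dB single-pass), so the order and cutoff
  are treated as the reproducible parameters and the achieved attenuation
  is reported rather than forced.
* **Edge handling.** Each pass uses odd-reflect padding sized to about
  three periods of the cutoff frequency, and the channel's edge value is
  subtracted before filtering so the filter state does not see a step.
  Without the cutoff-aware padding, a 5 Hz envelope smoother (settling time
  ~0.2 s) produces spurious edge transients.

Sparse series (lactate, and signal values between samples) are interpolated
with cubic Hermite splines using Catmull-Rom tangents: the tangent at knot
*i* is the centered difference of its neighbours, one-sided at the ends. The
interpolant is C1 and passes through every knot; it is *not* clamped to
non-negative lactate values — overshoot is reported instead, so the user
sees when the spline disagrees with physiology.

## Burst detection and stride cycles

Muscle activity arrives in bursts, one per stride. The detector rectifies
the channel, smooths it with a zero-phase 5 Hz low-pass (the linear
envelope), and takes activation moments A(i) as local maxima of the
envelope derivative and deactivations D(i) as local minima — the points of
steepest rise and fall. Candidates must reach a prominence of 0.2 x the
largest absolute derivative; same-type events closer than 0.4 s are merged
(strongest kept) and the sequence is reduced to strict A, D, A, D...
alternation. The defaults (5 Hz, 0.2, 0.4 s) are sized to running cadence
(roughly 60-110 strides/min); all are configurable. Taking derivative
extrema on the *envelope* rather than the raw signal is deliberate: the raw
derivative has extrema every half carrier cycle.

Stride cycles are anchored on the right biceps femoris (RBF), the first
muscle to fire in a stride: one cycle spans consecutive RBF activations.
BF, VM and VL of both legs are attached to each cycle by their activation
falling inside the window (earliest wins if several); SM and GM are
excluded from timing analysis but keep their frequency features. Cycles
missing any of the six muscles are flagged incomplete and skipped by the
timing aggregates, not imputed — the timing ratios are undefined on them.

## Features

**Frequency domain (36 per burst per channel).** The mean-removed burst is
transformed with an unwindowed DFT at native bin spacing; the one-sided
magnitude spectrum is normalized by its trapezoidal integral over
[0, Nyquist] to a unit-integral density over frequency. Features: RMS and
its backward difference dRMS (first burst: 0 by convention), instantaneous
frequency (zero crossings / 2 x duration), the density's mode, mean, SD,
skewness, kurtosis, its nine deciles, and 19 relative band powers on a
fixed overlapping grid — 23.44 Hz wide bands every 11.72 Hz from
23.44-46.88 Hz up to 234.4-257.8 Hz. Band powers integrate the continuous
density over fixed Hz edges rather than counting DFT bins: burst lengths
vary, so bin counting would make the band width depend on burst duration.
"Power" is the DFT magnitude by default, with a `squared` option; the
magnitude convention is primary and the switch documents the ambiguity.
Decile crossings are solved exactly within a bin (the cumulative of a
piecewise-linear density is piecewise quadratic).

**Time domain (51 per session or window).** Per complete stride: phase
shifts between nine muscle pairs (activation-time differences as fractions
of stride duration), active-time percentages of the six muscles, and the
RMS of each muscle over its active interval. Session aggregates are the
mean and SD (n-1 divisor) of each, plus nine right-left asymmetries
(absolute differences of leg means). The *time-event* subset (36 features)
drops every RMS-derived entry, making it amplitude-free and hence robust to
electrode impedance and gain differences. Because the published aggregate is
one vector per session while models are trained per segment, the package
also computes the aggregates over sliding stride windows (default 20
strides, hop 5) to give timing features a time axis; window = session
reproduces the whole-session vector exactly.

## Lactate change-point segmentation

Given lactate samples x(t_i), the model is a connected three-segment line
l(t) with breakpoints t' (lactate threshold) and t'' (maximal
accumulation): slopes a1, a2, a3 and intercepts b1, b2, b3 with the
continuity constraints a2 = a1 + (b1 - b2)/t' and a3 = a2 + (b2 - b3)/t''.
Substituting the constraints makes l(t) linear in (a1, b1, b2, b3) for
fixed breakpoints, so the fit enumerates all admissible breakpoint pairs on
a candidate grid (the observation times by default; a refinement factor
inserts uniform subdivisions), solves each by ordinary least squares, and
keeps the pair with minimal squared error. Design choices:

* **Exhaustive grid search** rather than continuous optimization: with ~15
  samples the objective is cheap, piecewise-smooth in the breakpoints, and
  the enumeration is exact. Refining the grid can only lower the minimum.
* **Admissibility**: at least two observations per segment, so each slope
  is identifiable.
* **Ties** go to the smallest t', then smallest t''; perfectly colinear
  data raise a "no distinct phases" flag.
* **No slope constraints** are imposed; instead a plausibility warning
  fires when the fitted pattern is not
  aerobic < accumulation and recovery < 0 — mirroring the visual check a
  physiologist would apply, and flagging sessions where the runner never
  reached maximal lactate.

Classes are assigned left-closed: class 1 on [0, t'], class 2 on (t', t''],
class 3 on (t'', t_max]. The boundary convention is arbitrary but must be
fixed; left-closed keeps the breakpoint sample with the phase that produced
it.

## Feature selection and the random forest

Features and the interpolated lactate target are min-max normalized per
session. Each feature's Spearman rank correlation r_s with the target (the
numeric class label in classification — ordinal by construction, since
aerobic -> anaerobic -> recovery follows time) is computed as the
product-moment correlation of mid-ranks, which reduces to the classical
1 - 6*sum(d^2)/(n(n^2-1)) without ties. |r_s| is used for selection: a
monotone-decreasing feature is as informative as an increasing one.

The sweep selects features with |r_s| >= tau for tau = 0, 0.05, ..., 1,
trains a random forest on each set and scores it out-of-bag (macro-average
one-vs-rest AUC for classification, R-squared for regression). The best tau
is the highest score, ties to the larger tau (fewer features). Two runtime
choices: scores are cached per distinct feature set (many taus select the
same set), and the sweep scores sets with 3 seedings while the final model
is refit with the full 10 — the scoring loop needs only to rank sets, and
three seedings rank them stably at these problem sizes.

Forests use 100 trees and 10 seeds (derived deterministically from the
master seed, so reports are byte-reproducible). Classification pools the
out-of-bag class-vote fractions across seeds before the ROC is built — one
ROC per model; AUC is computed by the rank identity (equal to the
trapezoidal area with ties counted one half). Regression averages the
per-seed out-of-bag R-squared. Selected features are validated with a
Kruskal-Wallis test across pooled classes, reporting H, p and per-class
mean ranks so the direction of the effect is visible (for the VL band
powers the class-2 mean ranks sit highest).

## The synthetic-session generator

No public dataset accompanies this problem, so the generator is a
first-class module with exact ground truth:

* **Lactate**: the connected three-segment line (defaults: baseline
  1.2 mmol/L; slopes 0.05, 0.35, -0.20 mmol/L/min; breakpoints 720 and
  1440 s in a 1800 s session) sampled every 120 s with Gaussian noise
  sigma = 0.3 mmol/L (point-of-care analyzer variability), clipped at 0.
* **sEMG**: per channel, a train of cosine-tapered bursts of band-limited
  Gaussian noise (carrier 60-140 Hz, duty 0.3 of the stride) on a shared
  jittered stride clock (1.1 s nominal period), with per-muscle offsets
  encoding the BF -> VM -> VL firing order (0, 0.15, 0.30 of the cycle;
  left leg +0.5). The ground-truth activation time is the center of the
  rising ramp — exactly where the envelope derivative peaks, so the
  detector's definition and the generator's agree by construction.
* **Class effects**: during the anaerobic phase the VL carriers shift up
  15 Hz and gain 20% amplitude. The generator also shifts VL carriers
  -10 Hz (+10% amplitude) during recovery: without a recovery effect the
  aerobic and recovery phases would be statistically identical and no
  classifier could separate them; physiologically, the median-frequency
  decline of fatigue outlasts exhaustion. Effects are injected only into
  the VL channels by default, reflecting that VL spectral features carry
  the discriminative signal; this is configurable.

What the generator does *not* emulate: motor-unit dynamics, motion
artifacts, electrode lift-off, inter-muscle crosstalk, or mechanistic
lactate kinetics. Passing tests on synthetic sessions therefore validate
the *pipeline* — detection accuracy, feature definitions, segmentation,
selection and evaluation machinery — not field performance on real runners.

## Problem sizes used by the test suite and acceptance script

The published study regime (12 runners, ~25-30 min sessions) is emulated at
sizes a single CPU handles comfortably: the pooled cohort runs 12
participants at 960 s sessions (breakpoints 360/720 s, proportional to the
full-scale defaults) with the VL channel that carries the injected effects,
giving ~870 bursts per runner and ~10,400 pooled rows. Breakpoint-recovery
simulations use the full-scale lactate defaults (1800 s, 2-min sampling,
200 replicates). Generator *defaults* remain the full-scale session; the
scaled cohort is a choice of problem size, not of effect size — the
injected spectral/amplitude effects and noise levels are identical at both
scales.

## Known limitations

* The burst detector assumes periodic, reasonably isolated bursts; heavily
  overlapping activations (e.g., co-contraction without a quiet phase)
  merge.
* The CPS model fixes exactly two breakpoints. Sessions without a recovery
  phase (runner stops at exhaustion) violate the model and are flagged by
  the plausibility warning rather than refit with fewer segments.
* Spearman-threshold selection is univariate; a feature informative only
  in interaction with another is invisible to the sweep (the forest at
  tau = 0 still sees it).
* Normalizing per session removes between-runner scale but also any
  absolute-level information; this matches the pooled-cohort design, where
  only within-session structure should drive the classes.
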