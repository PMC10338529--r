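---
title: "Methods: simulating, classifying and explaining ground reaction force curves"
author: "gaitsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, classifying and explaining ground reaction force curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

`gaitsig` implements a complete machine-learning analysis of stance-phase
ground reaction forces (GRF) in running.  The scientific question is whether
runners and footwear conditions leave recognisable *signatures* in the
tri-axial GRF: whether a classifier can recover (i) the subject-footwear
combination, (ii) the subject across footwear conditions, and (iii) the
footwear condition across subjects, and — via attribution of the trained
models — *which parts* of the stance phase carry that information.

The chain is: simulate (or read) raw force recordings → filter, crop to
stance, time-normalise and scale to body weight → classify with linear
support vector machines under a nested, task-stratified cross-validation →
decompose the predictions into per-input relevance scores → evaluate
footwear effects statistically, both over the whole curve (SPM-style
permutation ANOVA) and on the classical time-discrete variables.

## The synthetic cohort generator

Because per-trial laboratory force recordings are rarely shareable, the
package ships a parametric generator whose defaults define the study
conditions used throughout the tests: **30 subjects × 4 footwear conditions
(barefoot and three standardised shoes) × 10 trials = 1,200 recordings**,
sampled at 1,000 Hz.

Each subject carries a 9-parameter signature: vertical impact-peak
magnitude (population mean 160 %BW, between-subject SD 25) and timing
(13 %stance, SD 2), active-peak magnitude (250 %BW, SD 20) and timing
(45 %stance, SD 3), anteroposterior braking and propulsion magnitudes
(35 %BW, SD 6 each), mediolateral amplitude (8 %BW, SD 2.5) and phase
(SD 0.6 rad), and stance duration (250 ms, SD 20).  These magnitudes are
typical of rearfoot running at self-selected speed (active peak ≈ 2.5 BW,
contact ≈ 250 ms).  Body mass is drawn around 85.7 kg and truncated to
71.4–100 kg.  Footwear conditions act as additive offsets on the signature
(barefoot: higher, earlier impact peak, shorter contact; the three shoe
models: distinct smaller shifts) plus a body-weight delta for shoe mass;
body weight is stored per (subject, condition) pair, exactly as a per-trial
scale measurement would be.

The stance template is a minimal smooth parametric family reproducing the
canonical curve morphology.  The vertical channel is a broad support hump
with steep `sin^0.5` shoulders — so the 10 N detection threshold is crossed
within about a millisecond of nominal foot strike and toe-off — plus two
Gaussian lobes (impact, active); the anteroposterior channel is a negative
braking lobe at 25 %stance mirrored by a positive propulsion lobe at
75 %stance (equal magnitudes therefore cancel in the impulse); the
mediolateral channel is a tapered low-amplitude oscillation with a positive
(lateral) bias.  Lobe amplitudes are calibrated by a 2×2 linear solve so
the template attains the configured peak magnitudes *exactly* at the
configured peak times, which makes the generator usable as an analytic
oracle for the preprocessing tests.  Sign conventions (braking negative,
propulsion positive, vertical non-negative, mediolateral mean-positive) are
a documented choice of the generator.

Randomness is two-level: one seed draws the cohort (subject signatures),
and every trial uses its own seed derived deterministically from
(cohort seed, subject, condition, trial), so any subset of the dataset can
be regenerated independently and datasets are byte-identical across runs.
Trial noise (i) jitters the signature parameters, including stance
duration, with within-subject SDs scaled by `trial_noise_scale`, and
(ii) adds a smooth spline-interpolated perturbation (15 knots; 2.5 %BW on
V, 1.2 on AP, 0.8 on ML at scale 1), edge-tapered so stance detection
stays unambiguous.  Lead-in and lead-out segments of 100 ms of
sub-threshold noise flank the stance so detection is actually exercised.

What the generator does **not** emulate: running speed and its variation,
multi-peak pathological profiles, force-plate drift or calibration error,
bilateral asymmetry, fatigue, and any kinematic signal.  Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
structure it assumes — subject- and footwear-specific additive effects on a
smooth template — not that real cohorts will reach any particular accuracy.

## Preprocessing

* **Filtering.** Second-order Butterworth low-pass at 50 Hz, applied
  forward and backward (zero phase, doubled effective order, no cutoff
  correction).  Edges use odd (point-symmetric) reflective padding of
  `5·fs/cutoff` samples (100 at the defaults), long enough for the
  zero-state startup transient to decay below 1e-9 inside the pad.  The
  implementation is validated against the closed-form bilinear-prewarped
  magnitude response `1/(1 + (tan(πf/fs)/tan(πfc/fs))^4)`.
* **Stance detection.** Longest maximal contiguous run of filtered vertical
  force strictly above 10 N; ties go to the earliest run.  The strict
  comparison and the longest-run rule make the detector robust to the
  sub-threshold lead-in noise.
* **Time normalisation.** Piecewise-linear interpolation onto 101 evenly
  spaced points (0–100 %stance in 1 % steps).  Linear interpolation is the
  least-assumption interpolant; its error on band-limited curves at 250+
  samples per stance is below 1e-3, which the tests check against an
  analytic sinusoid.
* **Amplitude normalisation.** Division by the per-condition body weight,
  expressed in %BW.
* **Feature assembly.** Concatenation ML ∥ AP ∥ V → 303 values.
* **Min–max scaling.** Per input dimension (303 independent scalers),
  fitted exclusively on the training folds; test values are *not* clipped
  to [0, 1].  A training-constant input maps to 0 everywhere.  Per-input
  scaling is the standard machine-learning reading of min–max
  normalisation; per-channel or global scaling are the plausible
  alternatives, and the choice is deliberately isolated in one object so it
  could be swapped.

## Classification

The classifier is the L2-regularised L2-loss linear support vector
classification, fitted in the dual by coordinate descent with the standard
shrinking heuristic (implemented in C++; the tolerance default `eps = 0.1`
on the projected-gradient violation range and the one-vs-rest multiclass
scheme follow the conventions of this solver family).  One-vs-rest is also
a requirement of the explanation stage, which needs one weight vector per
class.  The intercept is an augmented, regularised feature.  The solver's
update order is shuffled by an internal deterministic generator, so fits
are reproducible and independent of R's RNG state.

Cross-validation is task-stratified, four outer folds:

* *subject × footwear* (120 classes): every (subject, condition) cell
  spreads its 10 trials equally over the folds (2 or 3 per fold);
* *subject* (30 classes): folds are footwear-disjoint — leave one condition
  out, so the model must generalise across footwear;
* *footwear* (4 classes): folds are subject-disjoint — 30 subjects are
  partitioned 8/8/7/7, so the model must generalise across people.

Inside each outer fold the min–max scaler is fitted on the training rows
only, and `C` is selected by an inner two-fold grid search over
`2^-5, 2^-4.75, …, 2^15` (81 values), maximising mean inner accuracy with
ties going to the smallest `C`.  The inner split respects the task's
disjointness rule where possible; for the subject task the three training
conditions cannot split evenly in two, so the closest realisable analogue
is used: conditions are divided 2/1 and both directions are evaluated and
averaged.  The headline statistic is the median accuracy over the four
folds, reported next to the zero-rule baseline (the frequency of the modal
training class; ties to the first-encountered label).

## Explanation (LRP)

For a linear model, layer-wise relevance propagation reduces to the product
rule `R_i = x_i · w_i`, using the one-vs-rest weight vector of the
recording's **ground-truth** class; the intercept is not distributed, so
`ΣR_i` equals the intercept-free decision score exactly (checked to 1e-9
relative).  Only positive scores are analysed; each explanation is
normalised to its own maximum (the most local reading of "normalised to
their respective maximum"; `normalize = FALSE` keeps raw signed scores for
users who prefer aggregating before normalising).  Aggregations sum the
normalised maps per input position — over everything, per class or per
subject — and fold into 101-point per-channel profiles and ML/AP/V channel
totals.

## Statistical evaluation

The time-continuous comparison of the four footwear conditions is a
pointwise one-way ANOVA over the 101 time points with family-wise control
by the permutation distribution of the maximum F (labels permuted across
curves, 1,000 permutations by default, giving 0.001 resolution at
α = 0.05); significant regions are maximal supra-threshold runs.
Permutation inference was chosen over random-field-theory thresholds
deliberately: it is assumption-light, exact up to Monte-Carlo error, and
self-contained.  Trials are pooled within conditions, i.e. treated as
independent curves; the repeated-measures structure of trials within
subjects is not modelled, which makes the per-curve degrees of freedom
optimistic for real cohorts — a known limitation shared with the common
usage of curve-level SPM ANOVA.

Time-discrete variables are extracted with fixed search windows: vertical
impact peak = first local maximum in (0, 33] %stance (marked missing when
absent, as in flat-impact profiles), active peak = global maximum after the
impact peak, braking peak = global minimum in (0, 50], propulsion peak =
global maximum in (50, 100), mediolateral extrema over the whole stance,
ties to the earliest index.  Differences between conditions are tested per
variable with the Kruskal–Wallis test (tie-corrected, χ² approximation)
and, when significant, with the Dwass–Steel–Critchlow–Fligner pairwise
post-hoc test: pairwise re-ranking, tie-corrected standardised rank sum,
referred to the studentised-range distribution with k groups.

## Problem sizes and numerical choices

The package's own validation uses scaled-down cohorts chosen to exercise
every code path at interactive speed: a 4×4×3 cohort for unit tests; 5-seed
parameter-recovery studies on 6×4×4 (null effects), 15×4×4 (strong subject
effects), 12×4×4 (strong footwear effects) and 10×4×4 (AP-only footwear
effects) designs with coarsened C grids (exponent steps of 2.5–10), since
accuracy is flat over wide C ranges on these problems; a 200-dataset null
study for the SPM family-wise error (24 curves, 200 permutations each).
The acceptance summary script runs the full 1,200-recording default design
with an exponent step of 2.5.  Degenerate inputs are handled by documented
rules rather than errors wherever the analysis can proceed: constant
scaler inputs map to 0, all-non-positive relevance maps stay zero, an
absent impact peak is missing data, fully tied Kruskal–Wallis input gives
H = 0.

## Known limitations

Synthetic effects are additive and smooth, so classification on the
default cohort is easier in some respects (no speed confound) and harder
in others (no idiosyncratic waveform features beyond the 9 parameters)
than on laboratory data; published accuracies from real cohorts are
neither expected nor reproduced here.  The subject task's inner
cross-validation cannot be fully condition-disjoint with three training
conditions.  The SPM ANOVA ignores the within-subject correlation of
trials.  The generator's stance template has a single stance per
recording; multi-step recordings and multi-plate segmentation are out of
scope.
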