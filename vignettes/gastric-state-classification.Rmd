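---
title: "Classifying gastric myoelectric state from serosal slow-wave recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gastric myoelectric state from serosal slow-wave recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(slowwave)
```

## The problem

The stomach generates a rhythmic myoelectric oscillation — the gastric slow
wave — whose frequency and power structure change with functional state.
In the ferret, the normogastric rhythm spans roughly 0.05–0.3 Hz (3–18
cycles per minute), and feeding shifts spectral power toward higher,
*tachygastric* frequencies.  `slowwave` implements a complete pipeline for
deciding, from one minute of multichannel serosal recording, whether the
animal is in a baseline (fasted) or feeding state:

1. a seeded synthetic-recording generator standing in for animal data,
2. a five-stage preprocessing and channel-quality chain,
3. 1-minute windowing with stratified cross-validation folds,
4. Welch band-power features with sequential feature selection feeding five
   shallow classifiers, and
5. a 1-D residual convolutional network trained end to end on the raw
   windows.

Classifier scores live in [0, 1] with 1 = feeding; performance is
summarized by ROC/AUC and by accuracy, sensitivity (feeding detection) and
specificity (baseline detection) at a 0.5 threshold under repeated
stratified 3-fold cross-validation.

## The synthetic generator: what it emulates, and what it does not

No public recordings exist for this preparation, so every stage is
validated against `generate_recording()` / `simulate_study()`.  The
generator is a *stated world*, not a tuning knob; its defaults are fixed
once and all tests run against them.

Each channel observes one shared gastric rhythm:

* an amplitude-modulated slow-wave sinusoid at `slow_wave_freq_hz`
  (default 0.15 Hz ≈ 9 cpm, mid-band of the ferret normogastric range) with
  amplitude 0.5 mV — well below the 2 mV artifact threshold, as serosal
  slow waves are;
* a tachygastric sinusoid at `tachy_freq_hz` (default 0.45 Hz) carrying a
  condition-dependent fraction of rhythm power: 5% at baseline versus 35%
  during feeding.  This is the *only* systematic difference between
  conditions, so any discrimination the pipeline achieves must come from
  the spectral shift;
* per-channel random phase lag and gain (0.7–1.3), mimicking four
  electrode sites viewing one source;
* independent white noise (SD 0.05 mV) and a slow baseline drift
  (0.1 mV at 0.01 Hz, below the 0.05 Hz filter corner).

Artifacts are injected at Poisson-distributed times: amplifier-saturation
episodes clipped to exactly ±187.5 mV (the acquisition input range), and
raised-cosine movement transients of 5–50 mV peak — above the ±2 mV
physiological range, so the interpolation rule fires.  Rates default to
2 saturations and 6 movement transients per hour per channel; the
channel-quality worked examples crank these up on a single channel.

What the generator does **not** model: interstitial-cell network dynamics,
within-session nonstationarity (a real feeding session has pre-food,
feeding, and post-food phases; here the whole hour is labeled uniformly,
matching the classification protocol being reproduced), emesis or nausea
states, and vagal or intestinal channels.  A green test therefore
establishes that the pipeline's mechanics recover a known spectral
contrast — it is *not* a claim about performance on animal data.

## Preprocessing

`run_preprocess()` applies, in fixed order: (1) anti-aliased decimation
from the native 2 kHz to 200 Hz (order-8 zero-phase Butterworth low-pass at
80% of the output Nyquist, then subsampling); (2) replacement of
amplifier-saturated samples (|x| ≥ 187.5 mV) with zeros; (3) a zero-phase
band-pass Butterworth filter, 0.05–0.7 Hz, applied forward and backward;
(4) linear interpolation across runs exceeding ±2 mV, using the nearest
in-range flanking samples (boundary runs take the nearest in-range value,
since a one-sided line is undefined); (5) per-channel quality control.
The stage order and parameters are recorded in a pipeline fingerprint on
the output.

Numerical choices worth knowing:

* **Filter order.** Unspecified upstream; default order 3 per pass (the
  forward–backward application squares the magnitude response), exposed as
  `filter_order`.
* **Filter realization.** The very narrow normalized band (0.05–0.7 Hz at
  200 Hz) makes transfer-function polynomial filtering ill-conditioned, so
  filters are designed as zero-pole-gain cascades of biquad sections and
  applied with odd-extension padding of three slow-wave periods per end.
* **Saturation boundary.** "At or beyond the rail", with a 1 nV slack:
  the anti-aliasing filter can leave a clipped plateau marginally below
  ±187.5 mV.  Samples a plateau edge misses are still far outside ±2 mV
  and are caught by stage (4); the two percentages stay disjoint counts
  because stage-2 zeros are in-range and are never re-flagged.
* **QC power units.** The inclusion criteria are: < 20% samples dropped,
  < 20% samples interpolated, and total in-band Welch power above
  `qc_min_power` (default 1000).  Published channel-quality tables report
  powers of 1e7–1e8 for sub-millivolt signals, which is dimensionally
  inconsistent with mV² densities; expressing the signal in microvolts
  reproduces those magnitudes and makes the 1000 floor discriminate dead
  channels from live ones.  Both the threshold and, implicitly, the units
  are configuration, not hard-coded truth.
* **Channel exclusion scope.** QC is evaluated per channel per recording;
  `segment_study()` then retains only channels passing in *every*
  recording, matching study-wide exclusion of a bad channel.

## Features and selection

Each 1-minute, 200 Hz window (12,000 samples per channel) yields one Welch
PSD per channel: 8 Hamming-tapered, mean-detrended segments at 50% overlap,
each zero-padded to 16,384 FFT points (bin spacing 0.0122 Hz).  A
single-segment mode is available; it has the periodogram's resolution and
is what the tone-localization tests use, since 8-segment averaging trades
resolution (≈0.075 Hz) for variance.  Each channel's PSD is normalized by
its total power *within that window* — normalization constants are never
shared across windows or animals; per-animal pooling is a documented
alternative reading, not the default.  The normalized PSD is summed into
10 equal-width bands spanning 0.05–0.7 Hz (width 0.065 Hz, half-open
except the last), giving 30 features for 3 retained channels.

Standardization uses training-fold means and sample (n−1) SDs only;
zero-variance features standardize to zero with a warning.

`sequential_select()` performs greedy forward or backward selection
minimizing the 3-fold cross-validated misclassification rate averaged over
Monte-Carlo repetitions (default 100), stopping at the first step without
strict improvement (tolerance 1e-6).  One convention is ours: on strongly
separated data many single features reach *exactly* zero cross-validated
error, and a naive first-index tie-break would select whichever tied
feature happens to sort first.  Ties within tolerance are therefore broken
by cross-validated log-loss, which prefers the feature that separates with
the largest margin.  On the default synthetic study this makes the first
forward pick a tachygastric band — where the standardized class separation
is genuinely largest — rather than the lower-indexed normogastric
complement band that normalization induces.

## Shallow classifiers

Six kinds share one interface: linear and RBF-kernel soft-margin SVMs
(solved exactly as the dual quadratic program; RBF width from the median
pairwise-distance heuristic, cost 1), LDA and QDA, unpenalized logistic
regression, and a 100-tree random forest (bagged CART, Gini impurity,
√p features per split).  SVM margins are mapped to probabilities by Platt
scaling with regularized targets, fitted on the training fold only; the map
is strictly monotone, so ROC curves and AUC are unchanged by calibration.

## The residual network

Five residual blocks, each: main path — kernel-121, stride-2 convolution
with symmetric padding 60, then batch normalization; skip path — kernel-1,
stride-2 convolution, then batch normalization; sum, ReLU, dropout
(rate 0.2 by default; placed after the block ReLU — placement relative to
the summation is not pinned down upstream and is config-flagged).  Output
channels run 6/12/24/48/96.  A kernel-1 convolution with batch norm then
collapses to one channel, whose flattened length is ⌈input_len/32⌉ — 375
for a 12,000-sample window — feeding a single fully connected unit and a
sigmoid.  Convolutions carry no bias (batch norm's shift makes it
redundant).  The default model has 750,054 learnable parameters, frozen as
a regression constant in the tests.

Training minimizes binary cross-entropy with AdamW (learning rate 0.001,
weight decay 0.01, batch 20, at most 200 epochs).  The held-out
cross-validation fold doubles as the early-stopping validation set — no
inner split is described upstream; an inner split would cost a third of
the training data and the optimistic-selection bias of reusing the fold
affects only *when* training stops, not the scores' fold hygiene.
Training halts once 50 epochs pass without a strictly lower validation
loss and returns the minimum-validation-loss checkpoint.  Everything is
seeded: initialization (He-style normals), shuffling and dropout masks.

Since no deep-learning runtime is available in this environment, forward,
backward and AdamW are implemented in R; convolutions are evaluated one
kernel tap at a time as dense matrix products over a batch stored as a
`channels x (length * batch)` matrix, which routes the arithmetic through
BLAS.  The backward pass is verified against central finite differences to
~1e-9 relative error in the tests.

## Evaluation

ROC curves sweep all distinct score thresholds with the midpoint tie
convention, so the trapezoidal AUC equals the pair statistic
P(score₊ > score₋) + ½P(tie); the tests assert this equality against an
O(n²) oracle.  Thresholded metrics use an inclusive boundary (score ≥ 0.5
predicts feeding).  `repeated_cv()` draws a fresh stratified fold plan per
repeat, pools each repeat's validation scores, and reports means and SDs
across repeats plus a per-subject breakdown; an audit log records which
sample ids every training-fold statistic (standardizer, selection,
classifier, posterior map) was fitted on, and the tests assert it never
intersects the validation fold.

Fold granularity follows the window-level protocol (480 windows, 3 folds,
stratified); windows of one animal can land in both training and
validation folds, which is leakage-prone across subjects — a
`group_by_subject` mode provides the conservative alternative and is off
by default.

## Reduced-scale acceptance settings

The acceptance tests size the expensive criteria for a single desk CPU:
the permutation-null battery keeps the full 480-window protocol but uses
2 repeats and asserts the chance band on the mean over three seeded
permutation draws — a single draw's cross-validated estimate carries a
dataset-level spread of a few percent plus the well-known pessimistic
bias of cross-validation on null data, so it can stray a point or two
outside [45, 55] without any leak being present.  The CNN is exercised by
the signal-recovery criterion rather than the null battery, which its
training time would otherwise dominate; the signal-recovery run uses 96
windows and 5 epochs of the ≤ 30 allowed.  At the default class
separation the network reaches validation AUC ≈ 1 by epoch 3.

## Known limitations

* The generator's stationary, two-line spectral model makes the
  classification problem easier than animal data; reported green tests are
  mechanics checks, not performance claims.
* Welch segmentation of a 60 s window has coarse (≈0.075 Hz) resolution;
  band features near band edges blur accordingly.
* The random forest and SVM are compact reimplementations (no library
  binding exists here); they follow the textbook algorithms but lack the
  engineering of mature libraries (e.g. shrinking heuristics, surrogate
  splits).
* QDA requires non-singular within-class covariances and will refuse
  degenerate feature sets rather than regularize.
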