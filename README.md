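# slowwave

Simulation, preprocessing and classification of gastric myoelectric
(electrogastrographic) recordings.

## What this is for

The stomach's myoelectric slow wave — roughly 0.05–0.3 Hz in the ferret —
shifts power toward higher (tachygastric) frequencies during feeding.
`slowwave` is for researchers who record multichannel serosal gastric
signals in freely moving animals and want to classify 1-minute windows of
signal as *baseline* vs *feeding*.  It provides the full path from raw
2 kHz multichannel CSV exports to cross-validated classifier reports:

* **`synth`** — a seeded generator of realistic synthetic recordings
  (shared slow-wave source across channels, condition-dependent
  tachygastric power fraction, amplifier-saturation episodes at
  ±187.5 mV, >2 mV movement transients), standing in for animal data that
  cannot be redistributed.
* **`preprocess`** — anti-aliased decimation to 200 Hz, zeroing of
  saturated samples, zero-phase Butterworth band-pass (0.05–0.7 Hz,
  applied forward and backward), linear interpolation of >2 mV artifacts,
  and a three-criterion channel-quality gate (< 20% dropped, < 20%
  interpolated, in-band Welch power above a floor).
* **`windows` / `spectral`** — 1-minute segmentation (12,000 samples per
  channel), stratified 3-fold plans, Welch PSDs (16,384-point FFT),
  per-channel normalization, and 10 equal-width band powers over
  0.05–0.7 Hz (30 features for 3 retained channels), with forward/backward
  sequential feature selection under a Monte-Carlo cross-validated
  misclassification objective.
* **`shallow`** — linear/RBF SVM (exact dual QP), LDA, QDA, logistic
  regression and a random forest, all scoring in [0, 1] (1 = feeding) via
  Platt-calibrated posteriors where needed.
* **`resnet1d`** — a 1-D residual CNN (five stride-2 blocks, kernel 121,
  channels 6/12/24/48/96, then a kernel-1 collapse to a 375-length feature
  vector, one fully connected unit and a sigmoid; 750,054 parameters),
  trained with AdamW, binary cross-entropy, batch 20, learning rate 0.001
  and patience-50 early stopping — implemented natively in R with
  BLAS-backed convolutions.
* **`evaluate`** — ROC/AUC (trapezoid = pair-count statistic), accuracy /
  sensitivity / specificity at threshold 0.5, repeated stratified k-fold
  cross-validation with fold-hygiene auditing, CSV reports.

The model at the core of the shallow path: for window $w$ with channel
PSDs $P_c(f)$ (Welch, normalized per channel), features are
$x_{c,b} = \sum_{f \in [e_b, e_{b+1})} \hat P_c(f)$ for 10 equal bands
$[e_b, e_{b+1})$ spanning 0.05–0.7 Hz.  The CNN instead learns features
from the raw window: each residual block computes
$\mathrm{ReLU}(\mathrm{BN}(W * x) + \mathrm{BN}(W_s *_2 x))$ with stride-2
convolutions, halving the 12,000-sample input five times to length 375.

## Worked example

Simulate a small study, preprocess, featurize, and cross-validate an
RBF-kernel SVM on the band-power features:

```r
library(slowwave)

## 4 subjects x 2 conditions, 12 min each (reduced from 1 h for the demo)
recs <- simulate_study(duration_s = 720, seed = 1)
cleans <- lapply(recs, run_preprocess)
cleans[[1]]
#> <clean_recording> subject F1, baseline: 4/4 channels retained @ 200 Hz
#>  channel pct_dropped pct_interpolated total_power passed
#>      ch1           0        0.1430556     8656868   TRUE
#>      ch2           0        0.0000000     9091604   TRUE
#>      ch3           0        2.2486111    14258467   TRUE
#>      ch4           0        0.1618056     7681596   TRUE

windows <- segment_study(cleans)      # channels retained in every recording
length(windows)
#> [1] 96

features <- featurize_windows(windows)
dim(features$values)
#> [1] 96 40

report <- repeated_cv(features, pipeline_spec("svm_rbf"),
                      n_repeats = 3, k = 3, seed = 1)
report
#> <metric_report> svm_rbf: 3/3 repeats, threshold 0.50
#>   accuracy    100.0% (SD 0.0)
#>   sensitivity 100.0% (SD 0.0)
#>   specificity 100.0% (SD 0.0)
#>   AUC         1.000
```

Read it as: every channel passed the quality gate (`pct_dropped` /
`pct_interpolated` are the percentages of samples zeroed at the amplifier
rail and interpolated beyond ±2 mV; `total_power` is the in-band Welch
power in µV²-scale units compared against the 1000 floor).  Segmentation
yields 96 one-minute windows (48 per condition); with all four channels
retained there are 4 × 10 = 40 band features.  At the generator's default
separation (tachygastric power fraction 0.05 baseline vs 0.35 feeding) the
SVM separates the conditions perfectly — the synthetic world is
deliberately easier than animal data; see the vignette for what that does
and does not establish.

Train the residual network on the same windows (minutes of CPU):

```r
plan <- make_folds(windows, n_folds = 3, seed = 1)
tr <- which(plan$assignments != 3); va <- which(plan$assignments == 3)
cnn <- build_model(cnn_config(in_channels = 4), input_len = 12000)
fit <- train_model(cnn, windows[tr], windows[va],
                   train_config(max_epochs = 5, patience = 4, seed = 1))
roc_auc(score_windows(fit$model, windows[va]),
        sapply(windows[va], `[[`, "label"))$auc
#> [1] 1
```

A command-line front end covers the file-based workflow:

```sh
slowwave simulate  --out-dir raw/ --seed 1 --duration-s 720
slowwave preprocess --in raw/F1_baseline.csv --out clean.csv --qc-report qc.csv
slowwave featurize --in cleaned/ --out features.csv
slowwave evaluate  --features features.csv --classifier svm_rbf --out reports/
```

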