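# ppgrr — respiratory rate from the photoplethysmogram

Respiratory rate (RR) is one of the earliest indicators of patient
deterioration, yet it is usually counted by hand or requires dedicated
instrumentation. A pulse oximeter's photoplethysmogram (PPG), recorded
continuously on almost every monitored patient, carries breathing in three
ways: baseline wander, pulse-amplitude modulation, and respiratory sinus
arrhythmia (beat-interval modulation). `ppgrr` estimates RR continuously
from the PPG alone.

The package implements the full pipeline as an R package for biomedical
signal-processing researchers:

* **Readers/writers** for three record dialects: monitor-style CSV pairs
  (high-rate `PLETH` signal + 1 Hz `RESP` reference), MAT containers with
  annotated breath onsets (capnography benchmarks), and bedside-collector
  JSON documents with manually keyed exhalation instants.
* **Preprocessing**: zero-phase Hamming-window FIR band-pass (0.1–0.4 Hz),
  60 s windows with 1 s shift, linear resampling 125 → 30 Hz, and
  per-window min–max normalization; labels in breaths per minute (brpm).
* **The regressor**: a dilated residual 1-D convolutional network. Its
  unit block (*RespBlock*) passes the input through three parallel
  branches of two dilated convolutions each and sums the branch outputs
  with the broadcast channel-mean of the block input:

  RespBlock(x) = Σ₃ᵦ₌₁ ReLU(Wᵦ₂ ∗d ReLU(Wᵦ₁ ∗d x)) + mean_c(x),

  where ∗d is dilated convolution (kernel 2, dilation 3). Stages stack
  RespBlock → stride-2 convolution → average pooling, doubling filters per
  stage (256, 512, 1024, 2048 at the selected configuration), and end in
  global average pooling → dense(86) → scalar RR. Training is Adam
  (lr 10⁻³, batch 256) minimizing MAE = (1/N) Σ |RRᵗʳᵘᵉᵢ − RRᵉˢᵗᵢ|, with
  ×0.1 learning-rate decay on validation plateau and early stopping. The
  network and its backpropagation are implemented in the package itself
  (RcppArmadillo), with a float32 im2col+GEMM training engine checked
  against a double-precision reference path and finite differences.
* **Protocol**: subject-wise k-fold cross-validation (no patient on both
  sides of a fold — asserted), per-group test withdrawal, checkpointing.
* **Evaluation**: MAE ± SD stratified by breathing group (slow < 12,
  normal 12–20, rapid > 20 brpm), Pearson correlation, Bland–Altman
  limits of agreement, box-plot five-number summaries with 1.5·IQR
  outlier counts, and SNR-robustness tables (baseline-wander artifacts
  injected at 20/15/10 dB).
* **Synthetic data**: a respiratory-modulated PPG generator with exact
  ground truth and SNR-calibrated artifact injection, so the whole
  pipeline is testable offline.

## Worked example

Six synthetic subjects spanning the three breathing groups, preprocessed
into labeled windows and scored against a simple spectral estimator
(periodogram argmax — useful as a transparent reference; the network is
trained the same way via `build_dilated_resnet()` + `train_estimator()`):

```r
library(ppgrr)
cohort <- make_cohort(6, duration_s = 90, seed = 1)
cohort_manifest(cohort)
#>   subject_id  group  rr_brpm    hr_bpm
#> 1       S001   slow 11.19571  92.78626
#> 2       S002 normal 17.28638  76.12570
#> 3       S003 normal 17.03291  97.34128
#> 4       S004  rapid 21.39590  82.37346
#> 5       S005   slow  7.13286  94.46902
#> 6       S006  rapid 23.06007 109.55484

ws <- preprocess_records(cohort)
ws
#> <window_set> 186 windows x 1800 samples, 6 subject(s)
#>   rr_true: 7.1-23.1 brpm; groups: normal=62, rapid=62, slow=62

est_rr <- apply(ws$x, 1, function(w)
  60 * dominant_frequency(w, 30, band = c(0.08, 0.62)))
stratified_report(ws, est_rr)
#> <eval_report> 186 windows
#>   group   n    mae     sd
#>    slow  62 0.1643 0.0317
#>  normal  62 0.1596 0.1278
#>   rapid  62 0.2280 0.1693
#>     all 186 0.1840 0.1270
#> Pearson r = 0.9997 (p = 2.53e-304)
#> Bland-Altman bias -0.1840, LoA [-0.4330, 0.0650]
#> abs-error five-number: 0.0329 / 0.0601 / 0.1643 / 0.2864 / 0.3959
#> outliers: 0 (0.00%)
```

The MAE is in brpm; the per-group rows mirror the slow/normal/rapid/all
stratification used throughout. Training the network end-to-end looks
like:

```r
sp  <- split_test_by_group(cohort, c(slow = 1, normal = 1, rapid = 1))
tr  <- preprocess_records(sp$train)
cv  <- cross_validate(function() build_dilated_resnet(), tr, k = 3)
mae_sd(cv$fold_maes)        # MAE ± SD across folds
```

A shell entry point with `synth` / `preprocess` / `train` / `eval`
subcommands driven by one YAML config lives at `inst/cli/ppgrr`.

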