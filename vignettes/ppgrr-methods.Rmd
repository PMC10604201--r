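---
title: "Estimating respiratory rate from the photoplethysmogram: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiratory rate from the photoplethysmogram: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgrr)
```

## The problem

Respiratory rate (RR) is among the most informative vital signs and among
the least reliably recorded: it requires dedicated instrumentation
(capnography, impedance pneumography) or error-prone manual counting. The
photoplethysmogram (PPG), by contrast, is acquired continuously on nearly
every monitored patient by a finger pulse oximeter. Breathing leaves three
distinct imprints on a PPG:

* **baseline wander** — intrathoracic pressure swings add a slow additive
  drift at the breathing frequency;
* **amplitude modulation** — stroke volume varies over the breath, so the
  pulse envelope waxes and wanes;
* **frequency modulation** — respiratory sinus arrhythmia speeds and slows
  the heart within each breath.

`ppgrr` implements a complete pipeline that turns raw PPG into windowed RR
estimates with a dilated residual 1-D convolutional network, together with
the preprocessing, subject-wise cross-validation protocol, stratified
evaluation, and SNR-robustness machinery around it, and a synthetic PPG
generator that makes every stage testable without any external recordings.

## Preprocessing chain

The chain follows the order: **filter → slice → resample → normalize**.

1. **Band-pass 0.1–0.4 Hz.** A linear-phase Hamming-window FIR isolates
   the respiratory band (6–24 brpm) and suppresses the cardiac fundamental
   (~1–2 Hz). The design contract is normative, not the tap count: gain
   within −3 dB of unity across 0.15–0.35 Hz and at most −20 dB at and
   above 1 Hz, verified by direct transfer-function evaluation at design
   time. The default of 1537 taps is the shortest Hamming design we found
   that meets the contract at 125 Hz; shorter filters fail the −3 dB bound
   near 0.35 Hz because the passband sits so close to DC. Filtering is
   applied forward–backward (zero phase) so windows stay aligned with
   their labels.
2. **60 s windows, 1 s shift.** RR is counted per minute, so one window is
   one minute; the 1 s shift yields `floor((T − 60)/1) + 1` windows from a
   `T`-second record (421 from 8 minutes).
3. **Linear resampling 125 → 30 Hz.** Cuts the model's input length to
   1800 samples per window at negligible information cost below 0.4 Hz.
4. **Per-window min–max normalization.** Each window is rescaled to
   [0, 1]. We normalize *per window* (not per dataset) so that inference
   on a new window never depends on dataset statistics; the labels stay in
   brpm. A constant window (a flat-lined sensor) has no scale and is
   returned as all 0.5 with a `constant` attribute rather than NaNs.

Labels come from whichever reference the source record carries: the mean
(optionally median) of a 1 Hz reference RR series over the window, or the
event count × 60/window-length for annotated breaths and keyed exhalation
marks. Intervals are half-open `[start, end)` so an event on a boundary is
counted exactly once.

## The network

The regressor maps a normalized 1800-sample window to a scalar RR in brpm.
Its unit block, the *RespBlock*, runs the input through three parallel
branches of dilated 1-D convolutions — each branch being two identical
layers (kernel 2, dilation 3 at defaults) with ReLU — and sums the three
branch outputs with the channel-wise mean of the block input broadcast
across filters. The mean shortcut needs no projection weights, gives every
block an identity-like gradient path, and forces the useful invariant that
a block with zeroed convolutions reduces to its input mean (which the
tests exploit).

Each stage is RespBlock → stride-2 convolution (kernel 3) → average
pooling (width 2), and the filter count doubles each stage from
`2^filters_c` (256 at the selected configuration). After `n_blk = 4`
stages: global average pooling, a dense layer of 86 units, and a scalar
linear output. The seven knobs (`n_blk`, `kernel_blk`, `d_blk`,
`kernel_dwn`, `filters_c`, `s_c`, `n_den`) carry their admissible integer
ranges in `dilated_resnet_config()`, and `bayes_search()` minimizes a
user-supplied objective over that box with either a random or a
sequential model-based backend.

Two wiring questions the block description leaves open were settled as
follows: the "vertically identical" second convolution is per-branch (not
shared), and pooling sits inside every stage. Both are configurable in
principle through the config object's geometry and neither affects the
contracts the tests pin down (shape preservation, the zero-weight limit,
output purity).

### Training engine

No deep-learning framework is available to R here, and the network *is*
the method, so the package carries its own engine. There are two
deliberately redundant implementations:

* a modular double-precision reference path (R orchestration over Rcpp
  convolution primitives) whose gradients are verified against central
  finite differences in the test suite, and
* a fused single-precision engine (`src/drn_fused.cpp`) that computes the
  identical forward pass and gradients with batch-wide im2col + GEMM; the
  tests pin its predictions, loss and gradients to the reference path at
  float tolerance.

Training is Adam (lr 0.001, batch 256) minimizing MAE in brpm — the same
quantity that is reported, so the loss curve is directly interpretable.
On a validation plateau (no improvement > 1e-3 for 10 epochs) the learning
rate is multiplied by exactly 0.1; training stops after 50 epochs without
improvement (both patiences configurable), and the best-validation weights
are returned. The scalar output bias is initialized at the training-set
mean RR so the network starts unbiased instead of spending hundreds of
sign-gradient steps drifting from zero. Subject-wise folds are near-equal
shuffled partitions of patient IDs; any subject appearing on both sides of
a fold is a hard error checked on every run, because window overlap makes
within-subject leakage catastrophic for apparent accuracy.

## Synthetic data: what it emulates and what it does not

`generate_ppg()` builds a cardiac pulse train from a fixed two-Gaussian
systolic/diastolic template placed at beat times driven by the modulated
instantaneous heart rate, then applies the three respiratory mechanisms:
additive baseline wander (`bw_depth`, default 0.2 of the unit systolic
peak), envelope amplitude modulation (`am_depth`, default 0.15), and
beat-interval frequency modulation (`fm_depth`, default 0.1), plus white
instrument noise (`noise_sd`, default 0.01). The template has fixed
duration in seconds — as the systolic complex approximately does in real
PPG — so frequency modulation changes the local duty cycle and therefore
leaves a genuine spectral line at the breathing frequency; a purely
phase-warped template would not, and would make FM invisible to any
band-pass method. Cohorts draw per-subject RR uniformly within each
breathing group (slow 6–11.5, normal 12–20, rapid 20.5–35 brpm) and HR
uniformly in 55–110 bpm.

`inject_artifact_to_snr()` adds a random multi-sinusoid wander in
0.05–1 Hz — the band of motion and baseline artifacts, deliberately
overlapping the respiratory band — scaled so the measured SNR (mean-squared
amplitude of mean-removed signals) hits the target exactly; injection
happens on the raw record, before the standard pipeline runs.

What the generator does *not* emulate: arrhythmia, dicrotic-notch
morphology variants, sensor saturation/clipping, disease- and
intervention-driven waveform changes, or non-stationary breathing within a
window. Passing tests on synthetic cohorts therefore demonstrate that the
pipeline and the network are implemented correctly and can recover RR
when the three modulation mechanisms carry it; they say nothing about
accuracy on real ICU recordings, which the cited benchmarks show is much
harder (the rapid-breathing band, in particular, lies partly above the
0.1–0.4 Hz passband, and errors there are irreducibly large for any
method built on this filter — visible in our synthetic results too).

## Numerical and protocol choices

* Half-open windows and label intervals; type-7 quantiles for the
  five-number summary; box-plot outliers beyond 1.5·IQR from the
  quartiles; Bland–Altman limits at bias ± 1.96·SD of (est − true);
  two-sided Pearson tests.
* "MAE ± SD" is across folds for cross-validation tables and across
  windows for single-run test tables; both are computed and labeled.
* Plateau threshold 1e-3 brpm, plateau patience 10, early-stop patience
  50 — the protocol source names none of these, so they are package
  defaults chosen at conventional values.
* Weight init is seeded He-style with zero biases; all stochastic steps
  (cohort draws, artifact draws, shuffles, init) flow from explicit seeds,
  and re-running any config reproduces manifests, histories and reports
  bit-for-bit on the same build.
* Degenerate inputs: constant windows normalize to 0.5 (flagged); a record
  with an entirely dead reference RR channel is rejected at read time;
  partially missing 1 Hz reference samples are linearly interpolated with
  a warning; records shorter than one window yield an empty, warned-about
  window set.

## Scaled-down verification experiment

The acceptance script and test suite train a width-reduced network
(`filters_c = 5`, `n_blk = 3`; ~268k parameters) on a 24-subject synthetic
cohort of 170 s records — 18 train/validation subjects × 111 windows ≈
2,000 windows, with 2 held-out subjects per breathing group — for up to 35
epochs with plateau decay, early stopping and best-validation
checkpointing. Validation is one shuffled subject fold (3 of the 18
subjects); with so few validation subjects the validation MAE is a noisy
model-selection signal — a real property of subject-wise protocols at
this scale, not an artifact of the implementation.

These sizes are the package's verification
scale: large enough that the network must genuinely learn the
frequency-to-rate mapping across all three groups, small enough to run on
one CPU in minutes. The held-out MAE, its improvement over the train-mean
predictor, and the degradation of MAE as injected SNR drops from 20 to
10 dB (averaged over 10 artifact seeds) are the quantities
`scripts/acceptance.R` writes out.

## Known limitations

* The simplified baselines (`build_baseline()`) are fixed seeded feature
  extractors with a ridge readout behind the common estimator interface —
  honest reference points and interface exercisers, not reproductions of
  the published architectures they are named for.
* The fused engine trains single-channel inputs only; multi-channel
  configurations fall back to the reference path.
* Rapid breathing above ~24 brpm is attenuated by the 0.1–0.4 Hz passband
  by construction; estimates there rely on the filter's transition band
  and degrade with noise. This is a property of the method, reproduced
  faithfully, not a defect of the implementation.
* Training is CPU-only and single-threaded by design; there is no GPU
  path, mixed precision, or distributed training.
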