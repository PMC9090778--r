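---
title: "Detecting sleep spindles with a slim 1D U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep spindles with a slim 1D U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlr)
```

## The problem

Sleep spindles are brief bursts of 11–16 Hz (sigma-band) oscillatory
activity, lasting at least 0.5 s, that mark N2 sleep in the EEG. They are
scored by visual inspection, which is slow and — even among trained
experts — only moderately reproducible. `spindlr` implements an automated
detector: a slim, fully convolutional 1D U-Net that maps a single-channel,
z-scored 100 Hz EEG segment to a per-sample probability of being inside a
spindle, together with the training recipe, the event-level evaluation
framework, and a synthetic EEG generator that makes the whole pipeline
testable without access to restricted polysomnography archives.

## Signal conditioning

Segments are conditioned exactly in this order:

1. **Band-pass** 0.3–30 Hz with a zero-phase Butterworth filter
   (`bandpass()`). The filter is designed as a prototype of order 5 and
   applied forward and backward, so the effective magnitude response is
   10th-order and the phase response is exactly zero — event boundaries
   are not shifted. The design uses the `signal` package; the
   forward–backward application extends the signal by *odd reflection*
   over `max(3 × order, fs / 0.3)` samples, at least one full period of
   the lowest passband frequency, so the start-up transient of the 0.3 Hz
   high-pass corner decays inside the padding rather than inside the data.
2. **Downsampling to 100 Hz** (`resample_to()`), implemented by Fourier
   resampling (spectrum truncation). Because step 1 has already removed
   all energy above 30 Hz — well below the 50 Hz output Nyquist — this
   method is exact for the retained band; we measured passband amplitude
   error below 1 % on test tones, whereas a generic polyphase resampler
   showed several percent of ripple. Upsampling is refused: the pipeline
   is a downsampling pipeline by construction.
3. **Per-segment z-transform** (`zscore()`), population convention
   (divisor *N*). At the corpus segment length of 11 500 samples the
   divisor convention is numerically irrelevant, but it must be fixed for
   reproducibility; constant segments are an error, never silent zeros.

The order matters and is asserted in the tests: z-scoring before
resampling would normalize against out-of-band energy that the subsequent
band-limitation removes.

## Model

The network (`model_config()`, `build_model()`) is an encoder–decoder U
with shortcut connections:

* Each **level** applies two composite layers of
  convolution → ReLU → batch normalization (in exactly that order), both
  with the same channel count. The default three-level model uses 16, 32
  and 64 filters; channel counts double per level.
* **Compression** is max-pooling with widths `pools = c(w1, w2)`
  (default `c(4, 4)`); "three levels" counts two pooled levels plus the
  bottleneck.
* **Expansion** is nearest-neighbor upsampling by the matching pool width
  followed by a convolution (kernel equal to that width) mapping to half
  the incoming channels, which are then concatenated with the matching
  encoder activations.
* The **head** is a width-1 convolution to two channels followed by a
  softmax, so the spindle and no-spindle probabilities sum to one at every
  sample. The softmax is computed in a numerically clamped form.

All convolutions are length-preserving ("same" zero padding). Inputs whose
length is not divisible by the pooling product are right-padded with zeros
before the encoder and cropped after the decoder; the 11 500-sample
(115 s) corpus segments exercise this path, since 11 500 / 16 is not an
integer.

**Kernel and dilation.** Every composite convolution has effective extent
`(kernel − 1) × dilation` samples. The default is kernel 9, dilation 1
(extent 8): with two such convolutions per level and pool widths
`(4, w2)`, the receptive field of a bottleneck neuron is
`80 + 68·w2` samples — 1.48 s, 3.52 s and 6.24 s at `w2 = 1, 4, 8` — and
extent 8 is the unique calibration consistent with all three of those
figures simultaneously (`receptive_field()` computes the closed form).
Kernel 3 with dilation 4 realizes the same extent at a third of the
arithmetic; the reduced configuration used in the parameter-recovery
experiment below uses it.

There is no deep-learning framework in this package's dependency set, and
the network is small enough not to need one: forward pass, backprop and
the optimizer are implemented directly, with the convolution kernels in
compiled code (one BLAS GEMM per kernel tap over submatrix views). The
compiled path is verified against a pure-R reference implementation, and
the full backward pass against central finite differences, at relative
tolerance 1e-4, in the test suite.

## Training

Training (`train_fold()`, `cross_validate()`) follows a fixed recipe:

* **Loss**: generalized dice over the two classes,
  `1 − 2·(Σ_l w_l Σ_n r_ln p_ln) / (Σ_l w_l Σ_n (r_ln + p_ln))` with
  `w_l = 1/(Σ_n r_ln)²`. The weights are floored at 1e-8 when a class is
  absent from a batch. The loss is computed on the *raw* probability
  track; moving-average smoothing belongs to inference only.
* **Optimizer**: Adam with learning rate 0.005, β₁ = 0.9, β₂ = 0.999,
  ε = 1e-8; minibatches of 12 segments, shuffled each epoch, last short
  batch kept (hence `steps_per_epoch()` uses a ceiling — 45 steps for the
  535-segment five-fold training set of the emulated corpus).
* **Initialization**: Kaiming-uniform, bound `sqrt(6 / fan_in)`.
* **Cross-validation**: 6 folds split by subject, never by segment;
  ten-segment subjects are dealt round-robin first so each fold receives
  an equal share, then the remaining subjects fill the folds to equal
  size at random under the run seed.
* **Early stopping / model selection**: after each epoch the full
  inference chain is run on the validation fold and summarized as F1-bar
  (below). The best epoch's parameters are kept; training stops after 300
  epochs without improvement or at epoch 800. The per-epoch validation
  metric is F1-bar by default; plain F1 at the 20 % threshold is
  available via `run_config(val_metric = "f1_20")`. One metric is used
  consistently per run and recorded in the history.

## From probabilities to annotations

`predict_events()` chains: moving-average smoothing of both channels
(nominal width 0.42 s; the sample count is forced odd — 43 at 100 Hz — so
the kernel is centered and cannot shift event boundaries; edges are
handled by symmetric reflection, which preserves constants), a pointwise
class decision (spindle iff its smoothed probability strictly exceeds the
no-spindle channel, i.e. the 0.5 rule; exact ties resolve conservatively
to no-spindle), and joining of consecutive positive samples into events
with the half-open convention `[onset, onset + duration)`. No
minimum-duration rule is applied by default — the 0.5 s minimum is a
property of the reference annotations, not of the detector — but
`min_duration` is available.

## Evaluation

Evaluation is by event, not by sample. A detected and a reference event
overlap by `|a ∩ b| / |a ∪ b|` (intersection over the joined span;
`relative_overlap()`). Matching (`match_events()`) is greedy one-to-one by
descending overlap, accepting pairs whose overlap strictly exceeds the
threshold. A per-reference "closest detection" rule could double-count a
single detection, so one-to-one matching is enforced; on random small
instances the greedy matcher agrees with an exhaustive optimal assignment
in well over 95 % of cases and never differs by more than one true
positive (property-tested against a brute-force oracle).

From the counts: recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
`F1 = 2TP/(2TP+FP+FN)`. Empty denominators follow the perfect-empty
convention (all three metrics are 1 when both sides are empty). The F1
curve over the threshold grid 0.05–1.00 (step 0.05) is summarized by
F1-bar, the trapezoidal integral normalized by the grid span so constant
curves integrate to their own value. The default reporting threshold is
20 % overlap. By-subject statistics (`subject_summary()`) pool events over
all of a subject's segments — density in spindles per minute and mean
duration — and `compare_summaries()` relates detector-derived to
reference-derived characteristics by Pearson's r, an OLS slope, and
Fisher's z.

`select_test_split()` reproduces the corpus's test-set construction: among
random by-subject candidate splits (ten-segment subjects always train,
cohorts equally represented in the test set), the candidate on which a
pluggable reference detector scores its *median* F1\@20 % is selected, so
the test set neither favors nor penalizes the baseline. A simple
sigma-power detector (`sigma_baseline_detector()`: sigma band-pass, moving
RMS, threshold at 1.8× the segment median, runs ≥ 0.5 s) stands in for
feature-based reference algorithms.

## The synthetic generator

`generate_dataset()` emulates the corpus the detector targets: 115 s
artifact-free N2-like segments at 100 Hz; 180 subjects in two cohorts
(younger/older) of which 30 contribute ten segments and the rest three;
per-subject spindle density drawn once from a two-mode mixture centered at
1 and 5.25 events/min (SDs 0.25 and 1, equal weights, truncated at
0.2/min); events uniform in 11–16 Hz, uniform in 0.5–1.5 s duration (the
lower edge is the scoring minimum, the upper edge exercises long events),
separated by at least 0.5 s. The background is 1/f colored noise
(spectral exponent α = 1, the classic EEG broadband slope). A spindle is
planted as a Hann-windowed sinusoid whose in-window RMS is `snr` times the
background's sigma-band RMS; `snr` defaults to 2 and is deliberately a
free axis, since the amplitude distribution of real consensus-scored
spindles is not published. The older cohort scales amplitude by 0.7 and
duration by 0.85 (clamped at 0.5 s) — generator conventions that reproduce
the qualitative age effect for testing per-cohort reporting, not
physiological claims.

What the generator does *not* emulate: non-stationary background,
artifacts, sleep-stage transitions, frequency chirps within spindles, or
realistic spindle morphology beyond a smooth envelope. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers planted
structure under controlled conditions, not that it matches published
performance on consensus-annotated recordings, which require a
controlled-access download and are out of scope here.

## Parameter-recovery experiment

The acceptance suite trains a reduced model (3 levels, filters 8/16/32,
kernel 3 with dilation 4 — the dilated equivalent of the extent-8
calibration) on a high-SNR (`snr = 5`) synthetic set of 24 subjects
(12 younger, 12 older, three segments each; 20 subjects train, 4 are the
early-stopping validation set), for at most 50 epochs with patience 15,
and evaluates F1 at 20 % overlap on 8 held-out subjects. The run must
reach held-out F1 ≥ 0.8 with a train−test gap below 0.1. These problem
sizes keep the experiment at desk scale while preserving the study's
structure (by-subject splits, two cohorts, batch size 12).

## Numerical choices and degenerate inputs

* Batch norm uses biased batch variance with ε = 1e-5 and momentum 0.1
  running statistics (used verbatim in inference mode).
* The two-class softmax is computed via a max-shift; probabilities are
  exact complements, so the indicator's argmax rule and the 0.5-threshold
  rule coincide.
* Ties in the class decision go to no-spindle (conservative detection).
* Constant segments are a z-scoring error; non-finite samples are
  rejected at the model boundary.
* `match_events` uses strict `>` comparison, so threshold 0 counts any
  positive overlap.
* All randomness flows through per-call seeds (`with_seed` internally);
  no function leaves the global RNG state modified.

## Known limitations

* Single-channel only; no scalp localization.
* The matcher's greedy rule is a documented deviation candidate from a
  per-reference closest-detection reading; the brute-force comparison
  bounds its effect.
* Published performance figures on consensus-annotated recordings are not
  reproduced here: they require restricted data access. The package
  reports what it computes on synthetic data and on analytic quantities
  (receptive fields, split arithmetic, loss values).
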