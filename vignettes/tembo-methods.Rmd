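---
title: "Classifying elephant call types from raw audio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying elephant call types from raw audio: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tembo)
```

## The problem

Asian elephants produce three broad call types that field biologists care
about: **rumbles** (very low-fundamental, harmonically rich social calls,
often partly infrasonic), **roars** (loud, noisy vocalizations produced in
intense social interactions), and **trumpets** (bright, high-fundamental
calls produced through the trunk). Automatically labelling short recordings
with one of these classes supports passive acoustic monitoring of wild
populations. `tembo` implements a complete, reproducible pipeline for this
task: data synthesis, preprocessing, augmentation, two classification routes
(raw waveform and spectrogram features), model-complexity profiling, and
Bayesian hyperparameter optimization.

The package follows two classification philosophies and lets you compare
them on equal footing:

* **Raw-waveform route.** Convolutional networks consume the 1-D waveform
  directly: a spatial/temporal feature-extraction network
  (`build_elephant_caller_net()`), a single-channel MobileNetV2 over a 2-D
  reshape of the waveform (`build_mobilenet_v2_raw()`), a 1-D
  depthwise-separable stack (`build_yamnet_1d()`), and a residual 1-D
  network (`build_rawnet_residual()`).
* **Spectrogram route.** MFCC and chroma constant-Q features are stacked
  into fixed-shape images and classified with a small 2-D CNN
  (`build_feature_cnn()`) or an RBF-kernel SVM (`fit_svm_spectral()`).

## Synthetic calls: what they emulate and what they do not

Licensed field recordings cannot ship with a package, so every stage is
exercised against a synthetic generator (`generate_call()`,
`generate_dataset()`) that emulates the three classes as acoustically
separable processes:

| class | fundamental (Hz) | harmonics | noise power share | AM rate (Hz) |
|---|---|---|---|---|
| rumble | 10–35 | 6 | 0.10 | 1–3 |
| trumpet | 300–800 | 8 | 0.15 | 4–8 |
| roar | 60–150 | 3 | 0.60 | 8–15 |

Each clip is a harmonic stack with 1/h amplitude roll-off and random phases,
mixed with white Gaussian noise at the class's power share, sinusoidally
amplitude-modulated, faded in/out over 50 ms, and peak-normalized to 0.9.
These defaults mirror the qualitative field descriptions of the call types —
rumbles are low and tonal, roars are noisy, trumpets are bright — while
keeping the classes separable by construction: a nearest-centroid classifier
on (spectral centroid, dominant frequency) exceeds 90% accuracy, which is
what makes downstream learnability tests meaningful. The default dataset
composition is 77 roars, 95 rumbles, and 63 trumpets (235 clips of 6 s at
16 kHz, mono PCM-16).

What the generator does **not** emulate: formant structure and vocal-tract
filtering, call-internal pitch contours, environmental reverberation and
propagation loss, overlapping callers, or recorder characteristics. A model
that is perfect on these synthetic classes has demonstrated only that the
pipeline can learn separable spectro-temporal structure end to end — it says
nothing about accuracy on field recordings, which is why published
real-data accuracies are not asserted anywhere in the test suite.

At sampling rates too low to carry a class's full harmonic stack the
generator caps the harmonic count below Nyquist; reduced-rate clips (e.g.
1 s at 8 kHz) are used throughout the tests to keep CPU budgets small, and
each test states the size it uses.

Per-clip randomness derives from a master seed through a counter scheme
keyed by class and index, so enlarging one class never perturbs another
class's clips.

## Preprocessing

Clips are trimmed of leading/trailing silence (frame RMS below −40 dB
relative to the loudest 25 ms frame, 10 ms hop — the thresholds are
package defaults, exposed as arguments), then standardized to a fixed
duration (default 6 s): long clips keep their leading segment; short clips
are zero-padded or tiled (`standardize_duration()`, idempotent by
construction). Trimming precedes standardization so that padding never
reintroduces silence the trimmer just removed.

The stratified split applies the 80:10:10 ratio within each class with a
deterministic rounding rule: training takes `floor(0.8 n)`; validation takes
the larger half (`ceiling`) of the remainder; test takes the rest. This rule
uniquely reproduces the reference split of the 77/95/63 composition —
(61, 8, 8), (76, 10, 9), (50, 7, 6) — and is property-tested for arbitrary
class sizes. Membership within the counts is randomized by seed.

## Augmentation

Three operators, each deterministic under its seed:

* `time_stretch()` — phase-vocoder time-scale modification (2048-sample
  Hann STFT, quarter-window hop); duration scales by 1/rate, pitch is
  preserved.
* `pitch_shift()` — resample by `2^(semitones/12)` then stretch back, so
  duration is preserved exactly and all frequencies scale.
* `add_gaussian_noise()` — white noise scaled to an exact measured SNR.

Two regimes reproduce the study designs. **Approach 1**
(`balance_classes()`) tops each training class up to a common target with
randomly parameterized stretch/shift copies; the default target is the
largest class rounded up to the nearest multiple of 10, which turns the
61/76/50 training split into 80/80/80 (240 clips) without hard-coding the
number. **Approach 2** (`expand_fourfold()`) gives every train/validation
clip exactly four variants — stretch, shift, both combined, and additive
noise — i.e. a strict five-fold expansion. The test split is never
augmented; both entry points refuse manifests containing test rows.
Parameter ranges (stretch 0.8–1.25, shift ±2 semitones, SNR 15–30 dB) are
mild perturbations chosen to preserve class identity of low-frequency calls.
Augmented clips are re-standardized to the pipeline duration so tensor
shapes stay fixed.

## Spectrogram features

`compute_mfcc()` uses 13 coefficients from a 128-band mel filterbank (HTK
mel scale), 2048-sample Hann frames with 512 hop and no centering
(`n_frames = 1 + floor((L − 2048)/512)`), power floored at 1e−10 before the
log so silence stays finite, orthonormal DCT-II. `compute_chroma_cqt()`
computes a semitone-resolution constant-Q transform (FFT-domain kernels, one
bin per semitone over six octaves from C1 ≈ 32.7 Hz — low enough to capture
rumble energy) on the same frame grid, folds bins into 12 pitch classes with
C = 0, and normalizes columns to maximum 1 (all-zero frames become uniform
columns rather than NaN). The two matrices are row-stacked into a
`(13 + 12) x n_frames` image; per-row z-scoring uses statistics fitted on
the training split only (`fit_feature_normalizer()`), and the leakage
direction is asserted in the tests. The 2-D CNN consumes the image; the SVM
consumes its flattening. None of the frame parameters is claimed to match
any external implementation — they are declared package defaults.

## The raw-waveform models

All four builders share one contract: input `(batch, input_samples)`
waveform matrices, output `(batch, 3)` probabilities summing to 1 (softmax
lives in the model head; training internally computes the cross-entropy in
the log domain on logits for numerical stability — an implementation
contract, not an architecture change).

**ElephantCallerNet-style network.** The spatial feature-extraction block
(SFEB) runs first — two strided 1-D convolutions (8 ch, k=9, s=2; 16 ch,
k=5, s=2, each with batch norm and ReLU) and a max pool of 4 — extracting
fine-grained frequency detail before temporal modelling. The temporal block
(TFEB) is five conv/BN/ReLU stages (32→64→128→128→256, k=3) with
interleaved max and average pooling (4, 4, 2, 2, 2). Because the two blocks
produce tensors of different shapes, the SFEB map is adaptively
average-pooled to the TFEB output length and concatenated along the channel
dimension; an integration conv/BN/ReLU stage (256 ch) with max pooling,
dropout (0.2), a 768-unit hidden layer and a 3-way softmax complete the
head. With the default 96,000-sample input this totals ≈4.9 M parameters,
inside the 4.2–5.2 M band around the published figure of the architecture
family; the exact published count is not reproducible because the original
layer table is not public, so the band is what the tests assert. All
conv/linear weights use Kaiming-normal initialization (variance 2/fan-in),
matched to the ReLU activations.

**MobileNetV2.** The standard width-1.0 inverted-residual stack, stem
adapted to one input channel and a 3-class head: exactly 2,227,139
trainable parameters, which the test suite and acceptance script verify by
summing the instantiated arrays. The waveform is reshaped to a
single-channel 300 × 320 grid (for 96,000 samples); the parameter count is
grid-independent, so the grid is chosen only for shape validity.

**YAMNet-style and RawNet-style networks.** A 1-D depthwise-separable stack
and a residual 1-D network (two conv/BN layers per block, LeakyReLU,
identity skip with 1×1 projection on channel change, no activation after the
addition so a zeroed block is the identity map). Their published parameter
counts are not targeted — the original layer tables are likewise
unpublished — so tests assert analytic counting identities instead.

### The network engine

No deep-learning runtime is part of the package's dependency set, so the
models run on a compact engine written in R: activations are
`(channels, height, width, batch)` arrays, convolutions are im2col gathers
followed by BLAS matrix products (1-D layers are 2-D layers with height 1;
full and depthwise groupings are supported), and every layer implements an
explicit reverse-mode gradient. Gradients are verified against central
finite differences in the test suite. Training uses Adam
(β₁ = 0.9, β₂ = 0.999) with per-epoch validation and best-checkpoint
selection; batch-norm running statistics follow the usual momentum-0.1
update. The optimizer choice and the 60-epoch default budget are package
defaults (the published configuration reports learning rates and batch
sizes — 32 train / 8 validation, which are the defaults here — but not the
optimizer); the per-model default learning rates are exposed by
`default_learning_rates()`.

### Profiling and quantization

`count_parameters()` sums all trainable arrays. `estimate_flops()` counts
analytically under a declared convention — 1 multiply-accumulate = 2 FLOPs,
bias adds counted, batch norm 2/element, activations 1/element, max pool
k−1 comparisons, average pool k+1 operations, softmax 5/class — and is
exactly linear in batch size; unsupported layers raise rather than
undercount. Published GFLOPS figures are not comparable across counting
conventions and are not asserted. `quantize_int8()` applies uniform
symmetric per-tensor weight quantization (127-step scale) to conv/linear
weights; inference uses the dequantized weights, the per-tensor error is
bounded by half a step, and the serialized size (float32 payload vs int8
payload + scale) drops below 0.35× — measured, not assumed, by
`model_serialized_size()`.

## Training-time sizes used in the tests

Everything runs on one CPU. The learnability check trains the
spatial/temporal network for 20 epochs on 30 synthetic clips per class at
1 s / 8 kHz (validation: 10 fresh clips per class) and requires ≥0.90
validation accuracy; this mirrors, at reduced clip length, the published
observation of validation accuracy reaching about 0.9 during training.
Comparison-harness tests use 0.25–1 s clips and 1–2 epochs: they assert
bookkeeping (grid cardinality, reproducibility, balanced manifests, test
split never augmented), not accuracy.

## Hyperparameter optimization

`run_hpo()` realizes Bayesian optimization with a Gaussian-process
surrogate: constant mean, Matérn-5/2 kernel with per-dimension length
scales and observation-noise jitter fitted by marginal likelihood
(L-BFGS-B on log parameters), expected improvement maximized over a seeded
candidate set — a Latin hypercube over continuous dimensions crossed with
enumeration of discrete choices (kernel size is never continuously
relaxed). Parameters are normalized internally (log10 for learning rate,
identity for dropout, index scale for choices). The default space is
learning rate ∈ [1e−4, 1e−2] (log-uniform), dropout ∈ [0, 0.5], kernel
size ∈ {3, 5, 7, 9}. The first `n_init` trials are quasi-random; failed
evaluations are recorded and skipped by the surrogate; duplicated
observations are harmless because of the jitter. The suite checks the EI
closed form, constraint satisfaction over random spaces, and that GP-EI
matches or beats random search at equal budget on a set of smooth 1-D
objectives (20 seeds). When tuning a model, the objective is best
validation accuracy from a short training run, keeping the loop desk-scale.

## Numerical choices and degenerate inputs

* Silence trimming never returns an empty clip (falls back to the input).
* MFCC log is floored; chroma columns of silent frames are uniform; both
  are asserted NaN-free.
* Softmax and the training loss are computed via the log-sum-exp shift.
* GP covariance matrices carry a 1e−8 diagonal jitter on top of the fitted
  noise.
* Pooling chains that would produce empty feature maps raise a shape error
  naming the stage; the feature-image CNN adapts its pooling to very small
  images instead of failing.
* WAV I/O is 16/24-bit PCM; 16-bit round-trips are exact to one
  quantization step (≤ 2⁻¹⁵).

## Known limitations

* The synthetic generator is a stand-in, not calibrated to any corpus; no
  claim about field-recording accuracy follows from green tests here.
* The R engine favours clarity and determinism over speed; it is adequate
  for the desk-scale sizes above but not for 6-s/16-kHz training runs at
  scale.
* Only WAV input is supported, and only mono processing (multichannel files
  are channel-averaged on load).
* The temporal block is implemented as the convolutional stack description;
  attention variants are out of scope.
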