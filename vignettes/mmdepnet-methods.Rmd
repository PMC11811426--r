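---
title: "Multimodal audio-visual depression screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal audio-visual depression screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Clinical depression screening from interview recordings uses two behavioural
channels: facial dynamics in video and prosody in speech. Depressed speakers
tend toward a lower, flatter ("monotonous") vocal pitch, and their facial
movement is reduced in amplitude. `mmdepnet` implements a three-part deep
architecture for this setting — a spatio-temporal-attention video network, a
graph-convolutional/recurrent audio network over MFCC frame-similarity
graphs, and an attention-based fusion network — together with everything
needed to exercise it end to end on a fully synthetic corpus: no clinical
data are required to test any part of the pipeline.

Each model predicts two targets jointly: a binary depression label, and a
PHQ-8 severity score (0–24). The binary label follows the questionnaire
convention that a score strictly above 10 indicates depression; the
generator exposes this boundary as `positive_threshold` (a score of exactly
10 is negative under the default).

# The video network

The backbone is a 3-D residual network. A 7×7×7 convolution with stride
(1,2,2) and a 3×3×3 max pool with stride (1,2,2) form the stem, preserving
the temporal extent and reducing space fourfold; four stages of residual
blocks follow (2,2,2,2 blocks for the 18-layer layout, 3,4,6,3 for the
34-layer layout), then global average pooling, a projection to the feature
vector `F_V`, dropout, and the dual head.

Inside every residual block, each of the two convolutional sub-modules is
followed by a temporal-spatial attention module (TSAM) before the residual
addition. A TSAM is the sum of two gated maps:

* **Temporal attention (TAM).** Global average and max pooling collapse
  each channel to a scalar; a shared two-layer bottleneck MLP (reduction
  ratio `attention_reduction`) scores both descriptors; the sigmoid of the
  summed scores is a per-channel weight that rescales the whole map. This
  is mathematically channel attention — the "temporal" name is kept from
  the architecture it implements.
* **Spatial attention (SAM).** Channel-wise mean and max maps are stacked
  into a two-channel image per time step and passed through a same-padded
  (1×k×k) convolution (k = 7 by default; the kernel has no temporal extent)
  and a sigmoid, giving one weight per position.

With all attention parameters at zero, both gates are exactly 0.5 and
`F_ts = 0.5·F_v + 0.5·F_v = F_v`: the attention network collapses to a
plain residual network at initialisation, a property the test suite asserts
network-wide to machine precision.

Counting TAM and SAM separately, the 18-layer layout carries
8 blocks × 2 sub-modules × 2 modules = 32 attention modules (hence
"tsnet32") and the 34-layer layout 64 ("tsnet64"). This counting convention
is the only one under which the two depth names are simultaneously
consistent with the block arithmetic; it is adopted here as a naming
convention.

Two geometry choices are deliberately configuration, not claims: the input
clip geometry (frames, resolution and stem padding are free parameters of
the architecture) defaults to same-padding and desk-scale 8-frame 32×32
grayscale clips; and the channel widths default to a small
`base_channels = 8` ladder (8/16/32/64) so that the network trains in
minutes on one CPU. Both scale up by configuration.

# The audio network

Speech is reduced to Mel-frequency cepstral coefficients computed in the
classical order: pre-emphasis (0.97) → 25 ms frames with a 10 ms hop →
Hamming window → FFT → power spectrum `|X|²/n_fft` → 26 triangular Mel
filters on exact bin frequencies → natural log with a floor of 1e-10 →
orthonormal DCT-II keeping 13 coefficients. Every numeric convention is
fixed in `mfcc_config()` and verified against an independently coded
naive-DFT oracle to 1e-6.

Each frame's MFCC vector becomes a graph node. Similarity is
`s = 1/(1 + d)` with `d` the Euclidean distance; an edge joins two frames
when `s ≥ 0.5`, which is the same as `d ≤ 1` — this single number
expresses both "high enough similarity" and "small enough distance". The
threshold's alternative reading (a bound on the distance itself) is exposed
via `threshold_on = "distance"`. Edge weights are the inverse distance,
capped at `weight_cap` (default 1e6) because identical frames would
otherwise produce an infinite weight.

The network stacks two graph convolutions using the symmetric-normalised
propagation rule with self-loops, `Â = D̃^{-1/2}(A_w + I)D̃^{-1/2}`,
`ReLU(Â X W)`, without bias — the de-facto meaning of "graph convolution"
when no propagation rule is otherwise specified, here on the weighted
adjacency. Node embeddings are then read in temporal frame order
(optionally strided via `subsample`; graph building also supports a frame
`stride`, default 2 in `prepare_corpus_data()`, to keep desk-scale
sequences near 100 steps) by an LSTM whose final hidden state — rather
than a mean over time, a documented alternative — feeds the projection to
`F_A`, dropout, and the dual head. Stacked (not interleaved) GCN→LSTM
ordering is implemented; an alternating arrangement would be a different
model.

# The fusion network

The two feature vectors are zero-padded at the tail to a common length d,
stacked row-wise into `H_VA` (2×d) and concatenated into `V_VA` (length
2d). A fully connected layer maps `V_VA` to two logits whose softmax
`V_VAF` weights the two rows: `F_VA = V_VAFᵀ·H_VA` is a convex
per-modality combination, so every fused entry lies between the two
modality entries. This is the only reading of "multiply the stacked
features by the attention vector" that is dimensionally coherent with a
per-modality attention interpretation; an elementwise sigmoid gate (one
weight per feature position) is retained behind `mode = "elementwise"`.
The fused vector is max-pooled (window 4 by default) and classified by the
dual head.

Training is staged: the two branches are trained first at the branch
learning rate, then frozen while the fusion parameters train on cached
branch features at the (lower) fusion rate — the two distinct stage
learning rates presuppose exactly this staging. Within the fusion stage the
readout heads form their own parameter group at twenty times the attention
rate (`head_lr_mult`). The reason is quantitative: AdamW bounds each
parameter's per-step movement by the learning rate, so over a linearly
decaying schedule the total movement budget is roughly half the initial
rate times the iteration count. The fusion heads act on a compact
max-pooled vector and need logit shifts of a few units to calibrate the
classification threshold; without the multiplier their budget is smaller
than that, and the fused F1 fluctuates with the initialisation even when
the fused AUC is essentially 1. The larger head rate improves training-set
fit (both F1 and severity RMSE) uniformly across initialisations. The
fusion head carries no dropout — regularisation lives in the branch
backbones.

# Training protocol

The reference protocol is AdamW (decoupled weight decay 0.01, no decay on
biases or normalisation parameters), binary cross-entropy plus PHQ-8
mean-squared error with unit weights, learning rate 1e-4 for the branches
and 5e-5 for fusion, linear decay to 1% over the run, 5000 iterations.
These are the defaults of `train_config()` and suit full-resolution
clinical corpora.

Small synthetic corpora cannot justify 5000 iterations of a deliberately
small network, so `desk_train_config()` compresses the same trajectory: 500
iterations at a tenfold branch rate (1e-3), and a full-batch fusion stage
at 2e-3 — with the whole training set in every step the gradient noise is
gone and a proportionally larger step is appropriate. All synthetic-corpus
results in the tests and the acceptance script use this protocol with the
problem sizes stated there: a 32-subject corpus for the overfit check and
200-subject corpora (8-frame 32×32 clips, 2 s of audio at 16 kHz) for
signal recovery, with 350 branch iterations for the latter.

The divergence guard aborts when the joint loss exceeds 1e6; a NaN
anywhere in the video activations raises an error naming the stage.

# The synthetic corpus

The generator emulates exactly the class-conditional structure the method
assumes, and nothing else:

* **Audio.** A harmonic complex (fundamental plus two harmonics) whose
  pitch follows a discretised Ornstein–Uhlenbeck process. Label-1 subjects
  get a lower mean fundamental (165 − 12·e Hz at effect size e, subject
  jitter sd 6 Hz) and a smaller stationary pitch sd (14·exp(−0.35·e) Hz):
  both the "lower" and the "monotonous" aspects of depressed speech.
  Additive Gaussian noise throughout.
* **Video.** A 2-D Gaussian blob oscillating smoothly; label-1 subjects
  get a smaller oscillation amplitude (factor exp(−0.35·e)) and slightly
  lower frequency (factor exp(−0.15·e)) — reduced facial dynamics. Pixel
  noise sd 0.02, values clipped to [0,1].
* **Metadata.** Exactly `round(prevalence·n)` positive labels; PHQ-8 drawn
  uniformly on the side of the threshold the label dictates; sex
  independent Bernoulli(0.5), enabling grouped evaluation. Splits are
  allocated by largest remainder in the proportions 163:56:10 and
  stratified by label.

At effect size 0 the class-conditional distributions coincide; at effect
size 3 an autocorrelation pitch tracker separates the classes at p ≪ 0.01
and a single threshold on inter-frame motion energy classifies clips with
accuracy above 0.9 — the separability gradient the tests rely on. The
effect-size scaling (a ~22% pitch gap and a ~65% amplitude reduction at
e = 3) was chosen once so that e = 1 is a plausible weak clinical signal
and e = 3 a strong one.

Determinism is a contract: every subject's signals derive from a seed
computed from the config seed and the subject index, so the same
configuration yields byte-identical corpora. Clips are stored as
uncompressed-semantics array containers (RDS with a named `frames` array)
precisely to avoid video-codec nondeterminism; audio is 16-bit PCM WAV.

What the generator does **not** emulate — faces, phonetic content,
inter-subject correlation, label noise, missing modalities — bounds what
green tests mean: they show the architecture can extract and fuse the kind
of signal the method posits from data that carries it, not that it works
on clinical recordings.

# Evaluation, ablation, attribution

`compute_metrics()` implements precision, recall, F1 (harmonic mean), RMSE
and MAE from their defining formulas, the ROC by threshold sweep and AUC by
the trapezoid rule; a single-class truth vector yields a missing AUC, never
zero. The classification threshold for F1 sits at probability 0.5 (logit
0); labels are never re-derived from the regression head. `grouped_eval()`
repeats the metrics per subject group (sex, by default) plus the mixed
union; `ablate()` trains the variant grid (`no_tsam`, `gcn_only`,
`lstm_only`, `video_only`, `audio_only`, `fused`) on identical splits and
seeds, sharing branch models where variants coincide.

`integrated_gradients()` uses a midpoint Riemann sum along the straight
path from baseline to input, which is exact for linear models at any step
count and satisfies the completeness axiom within 1% at 256 steps on the
smooth audio network. Per-frame feature tables (action-unit, gaze and pose
columns recognised by prefix) can be attributed against a logistic probe
via `attribute_frame_features()`, with window aggregation (default 100
frames) and per-group totals.

# Numerical choices and edge cases

* Max-pool ties break to the first occurrence, making backward scatter
  deterministic.
* Batch normalisation uses eps 1e-5, momentum 0.1, running statistics in
  evaluation mode; with identical parameters the attention-free and
  zero-attention networks are bit-identical in both modes.
* The LSTM forget-gate bias initialises to 1; masked (padded) sequence
  steps pass state through unchanged, so trailing zero-feature nodes do
  not alter the readout.
* `1/d` edge weights are capped rather than special-cased so the graph
  stays finite for duplicated frames.
* Seeds derived from user seeds stay below 2^31.

# Known limitations

The engine is plain reverse-mode code in R with C++ convolution kernels:
adequate for the desk-scale corpora it targets, not for full-resolution
video. Single-channel clips are the tested path. The PHQ-8 regression on
synthetic data shares its signal with the label, so severity RMSE mostly
tracks classification quality rather than an independent severity signal.
The fusion stage trains on frozen branches; joint fine-tuning is possible
through the same gradient machinery but is not the tested default.
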