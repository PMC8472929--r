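---
title: "Methods: GASF encoding and the improved residual network"
author: "gasfnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GASF encoding and the improved residual network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasfnet)
```

This vignette is the package's own account of its method: the model, its
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## The classification problem

Single-lead wearable ECGs produce long rhythm strips in which seven common
patterns are to be recognized: atrial fibrillation (AF), atrial tachycardia
(AT), normal sinus rhythm (N), premature atrial contraction (PAC),
premature ventricular contraction (PVC), sinus bradycardia (SBR) and
ventricular tachycardia (VT). The distinguishing features are a mixture of
rate (SBR slow; AT/VT fast), rhythm regularity (AF grossly irregular; PAC
and PVC interject premature beats), and beat morphology (PVC/VT
wide-complex; AF lacks P waves). Rather than hand-engineering those
features, the method turns each fixed-length segment into an image and lets
a convolutional network learn them.

## GASF encoding

A segment $x_1,\dots,x_n$ is min–max rescaled to
$\tilde x_i \in [-1, 1]$, compressed to $S$ points by piecewise aggregate
approximation (PAA: $S$ consecutive frames of near-equal cardinality,
remainder to the leading frames, each replaced by its mean), and mapped to
polar angles $\varphi_i = \arccos \tilde x_i \in [0, \pi]$. The Gramian
angular summation field is

$$G_{ij} = \cos(\varphi_i + \varphi_j),$$

a symmetric $S \times S$ matrix with entries in $[-1,1]$ whose diagonal is
$\cos 2\varphi_i = 2\tilde x_i^2 - 1$ — time runs along the diagonal and
the series' magnitude is recoverable from it, so the encoding preserves
temporal dependence while exposing 2-D texture (rate appears as band
spacing, QRS width as band thickness, irregularity as broken periodicity).

Numerical conventions:

* a constant segment has no scale; it is rescaled to all zeros, with a
  warning, rather than dividing by zero;
* polar inputs within $10^{-12}$ of $\pm 1$ are clamped (floating-point
  guard); anything further out is an error, since it indicates the caller
  skipped rescaling;
* whether rescaling is per segment (the default and only implemented
  choice) or per record was an open design point; per segment makes each
  image self-normalized and independent of record-level drift;
* the image side $S$ defaults to 224 (the canonical ResNet input). The
  desk-scale benchmark uses 64, which preserves the class-distinguishing
  texture while cutting compute ~12-fold per image.

Segmentation uses half-open windows $[s, s + w)$ at 0-based starts
$0, \text{stride}, 2\cdot\text{stride}, \dots$; the window defaults to 2000
samples — the block size the downstream classifier consumes — and the
stride defaults to the window (non-overlapping), since nothing in the
method requires overlap. Both are configuration parameters.

## The improved residual network

The baseline is the canonical bottleneck ResNet-50: a 7×7 stride-2 stem
with 3×3 stride-2 max pooling, four stages of (3, 4, 6, 3) post-activation
bottleneck blocks computing $H(x) = F(x) + x$, global average pooling and a
linear head. `build_baseline_resnet50()` reproduces its published
parameter count exactly (25,557,032 at 1000 classes, RGB input), which the
test suite uses as an independent wiring oracle.

`build_improved_resnet()` modifies the baseline in four ways:

1. **Five auxiliary shortcut groups**, all 1×1 convolutions merged by
   addition: one across each stage, with strides (1, 2, 2, 2) — stride 1
   for the first stage because its spatial size is unchanged — and one
   global branch from the stem output to the last stage output with
   stride 8. They give gradients short paths across whole stages, turning
   the learning target into residuals-of-residuals.
2. **Downsampling on the 3×3 convolution.** A stride-2 1×1 convolution
   reads only a quarter of its input positions; the stride is therefore
   moved to the 3×3 convolution, and the downsampling blocks' bypasses
   become 2×2 average pool (stride 2) followed by a stride-1 1×1
   convolution, so the bypass aggregates rather than discards.
3. **Pre-activation blocks**: batch normalization and the activation are
   moved ahead of each trunk convolution, leaving the merge a pure
   addition (zeroing a trunk makes the block exactly the identity — a
   tested invariant).
4. **SELU** replaces ReLU: $\lambda x$ for $x \ge 0$,
   $\lambda\alpha(e^x - 1)$ for $x < 0$, with $\alpha \approx 1.6733$,
   $\lambda \approx 1.0507$. For standard-normal input its output has mean
   $\approx 0$ and variance $\approx 1$ (tested empirically at $n = 10^5$),
   which keeps deep activations self-normalized and avoids dead units.

Choices the architecture description left open, fixed here:

* **Merge semantics of the auxiliary branches**: each branch output is
  added at its span's end, before the next stage's first pre-activation.
  Branches carry a batch-norm after the 1×1 convolution but no activation,
  keeping them near-linear like the block bypasses.
* **Global-branch junction**: the stride-8 branch is added after the last
  stage's output (including that stage's own shortcut), before the final
  pre-activation norm of the head.
* **Input channels**: GASF images are single-channel; the stem convolution
  takes 1 channel (configurable).
* **Head and loss**: global average pool, linear layer, softmax
  cross-entropy — the standard choice, since none was specified.
* **Channel widths**: canonical ResNet-50 widths (64/128/256/512 mid,
  ×4 out), scaled by a `width` multiplier so reduced benchmarks keep the
  topology.
* **Initialization**: seeded He-normal fan-in scaling for ReLU networks,
  LeCun-normal for SELU (the scaling under which SELU's fixed point
  applies).

The engine materializes a declarative `resnet_spec` into a flat
computational graph, validates every merge junction (channel counts and
cumulative strides must agree — a mismatch errors naming the branch), and
trains with hand-derived backpropagation; convolutions and pooling run in
compiled (RcppArmadillo) code. Analytic gradients are tested against
numerical differentiation through the full improved graph.

## Training protocol

Defaults mirror the development protocol: Adam, learning rate $10^{-4}$,
batch size 32, 150 epochs, cross-entropy, stratified 8:2 split. Splitting
takes `floor(ratio * n)` per class on the training side — the one rounding
rule consistent with the development corpus's published per-class
allocation (e.g. 328 → 262, 2106 → 1684). Test accuracy is recorded after
every epoch; note this means the test set doubles as a validation set, as
in the original protocol — learning curves should be read accordingly.
Determinism is per machine: identical seed, data and configuration
reproduce identical histories on the same BLAS; cross-platform bit
equality is not promised.

## The synthetic generator

`rhythm_spec()`/`generate_rhythm()` emulate the *statistics* that separate
the seven classes, not cardiac electrophysiology. Beats are sums of three
Gaussian bumps (P at phase 0.20 of the cycle, QRS at 0.40, T at 0.65; the
QRS width parameter sets the central bump at ~4 standard deviations). RR
intervals are drawn around a per-record base rate sampled from the class
band, with multiplicative jitter at the class's RR coefficient of
variation. Ectopic beats (PAC/PVC) substitute their own template at 60% of
the normal interval followed by a 140% compensatory pause, preserving the
mean rate. AF adds a 4–9 Hz band-limited fibrillatory baseline and has
zero P amplitude. All classes receive additive white noise, 2% of QRS
amplitude by default. Class bands: N 62–98 bpm (CV 3%), AF 100–150 (CV
25%), AT 150–200 (CV 2%), SBR 40–55, VT 150–210 with 160 ms QRS; PAC/PVC
are sinus-rate with 25% ectopy. These are textbook ranges chosen once;
constructor invariants reject parameterizations that would blur the class
definitions (e.g. an AF spec with regular RR, or a narrow-complex VT).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: realistic P/QRS/T morphology variation between
patients and leads, baseline wander and electrode artifacts, rhythm
transitions within a strip (every strip is single-rhythm), conduction
patterns (flutter waves, bigeminy timing, fusion beats), and inter-beat
morphology correlation. Results on synthetic data demonstrate that the
pipeline is wired correctly and that the architecture can learn
rate/regularity/morphology texture from GASF images; they say nothing
about clinical performance.

As a separability guard, a deliberately simple rule classifier (peak
detection, then rate / RR irregularity / complex width at 30% height)
achieves over 90% on generated segments; if the generator's classes ever
drifted closer together, that test would fail before any network test
became meaningless.

## Desk-scale benchmark

Full-scale training (ResNet-50 at 224×224, 150 epochs, ~10⁴ images) is far
beyond a test suite, so the package defines a fixed benchmark, chosen once,
as `pipeline_config()`'s defaults: the development corpus's class
proportions at 1% (117 segments), 64×64 images, the improved variant with
block plan (1, 1, 1, 1) at quarter width (~430k parameters), Adam at
learning rate 5×10⁻⁴, batch 16, 18 epochs, seed 1. The learning rate is
higher and the epoch count lower than the full-scale protocol because the
benchmark sees only ~100 minibatches in total; 18 epochs is where the
benchmark's training loss reaches its floor — beyond it, constant-rate
Adam merely oscillates in minibatch noise. At these conditions the run
finishes in under a minute on one CPU with held-out accuracy above 90%,
and the 10-epoch moving average of training loss is non-increasing.

Rare classes keep the corpus's imbalance: PAC and VT have 2–3 training and
1 test segment each, so single-sample flips move per-class metrics by
whole percentage points; undefined ratios (0/0) are reported as
`undefined`, never imputed.

## Evaluation conventions

Rows of the confusion matrix are the real category, columns the predicted.
Per class, with TP/FP/FN/TN from that matrix: precision TP/(TP+FP),
sensitivity TP/(TP+FN), specificity TN/(TN+FP), F1 the harmonic mean of
precision and sensitivity, accuracy (TP+TN)/total. Percentages are
reported at one decimal, rounding half away from zero (matching the
convention of the published tables this package checks against); macro
averages are unweighted means over classes, and micro accuracy is
trace/total. Any metric with a zero denominator is flagged undefined and
poisons the corresponding average rather than being silently zeroed.

## Known limitations

* The WFDB reader covers signal formats 16 and 212 and the standard beat
  annotation codes — enough for the common arrhythmia corpora — not the
  full format zoo (8/80/310/311, multi-segment records, aux strings are
  skipped rather than surfaced).
* Training is CPU-only and single-threaded apart from BLAS; the engine is
  written for correctness and reproducibility at benchmark scale, not for
  full-scale training throughput.
* The test-set-as-validation protocol (above) is reproduced faithfully
  rather than corrected; add a third split for methodological work.
* Class labels of synthetic strips are record-level; mixed-rhythm strips
  and annotation-driven labeling of real data are supported through
  `label_segments()` with a majority rule (ties broken by canonical class
  order), which is itself a convention the user can replace.
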