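---
title: "Methods: multi-task multi-stage temporal convolutional networks for joint phase/step recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task multi-stage temporal convolutional networks for joint phase/step recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`surgtcn` re-implements a complete surgical-workflow-recognition pipeline:
a two-level phase/step label ontology, a frame-level multi-task visual
backbone contract, a multi-task multi-stage causal temporal convolutional
network (MTMS-TCN), an online (streaming) inference path, the frame-wise
evaluation protocol with video-level cross-validation, and a synthetic
hierarchical-workflow generator that replaces the private study dataset for
all testing. This vignette documents the model, its assumptions, the
parameter choices and the numerical decisions; the README shows a worked
example with output.

## The label space

A *hierarchy* binds `P` phases and `S` steps; every step has exactly one
parent phase (`hierarchy()`, `parent_phase()`). The bundled default ontology
(`default_hierarchy()`) has the reference shape: 11 phases, 44 steps, a
subset of steps flagged clinically critical. Ids are 0-based and contiguous.
A *timeline* is a per-frame `(phase, step)` label track; a frame is
hierarchy-*inconsistent* when its step's parent differs from its phase label
(`validate_timeline()`). Labels outside the ontology are treated as a bound
error (wrong ontology), not a violation.

## Backbone contract

The frame-level backbone is a multi-task classifier: a shared trunk with one
linear softmax head per task, trained on individual frames with

* **median-frequency class balancing** per task:
  `w_c = median(freq of present classes) / freq_c`, frequencies per frame on
  the training split; classes with zero frames get weight 0 (they cannot be
  learned, and an infinite weight would poison the loss) and are excluded
  from the median;
* class-weighted cross-entropy per head and total loss
  `L_total = L_phase + L_step` (equal task weights);
* the reference recipe: 30 epochs, learning rate `1e-5`, L2 weight penalty
  `5e-5`, batch size 32, horizontal flip (p = 0.5), saturation
  `[0.75, 1.25]` and rotation `[-10°, 10°]` augmentation
  (`backbone_config()`).

The trunk is pluggable. A ResNet-50-class trunk as used at study scale is
not trainable on a desk CPU, so the package ships a compact three-block CNN
(`trunk = "small-cnn"`: stem average pooling, `3x3` conv + ReLU + `2x2`
average-pool blocks, global average pooling, one fully connected layer to
`N_f`). The temporal model only sees the feature *contract*: one
`N_f`-dimensional vector per frame, exchanged through a float32
little-endian row-major container with a JSON sidecar
(`write_features()` / `read_features()`), so externally computed features
can be substituted without code changes.

## MTMS-TCN

`mtms_tcn()` fits the temporal model on whole per-video feature sequences
(no temporal chunking). One *stage* is

1. a `1x1` projection of the stage input to `C` channels;
2. `L` dilated residual layers; layer `l` applies a **causal** dilated
   convolution (kernel `k`, dilation `2^(l-1)`, zero padding entirely in the
   past), ReLU, a `1x1` convolution, dropout, and a residual connection;
3. one `1x1` softmax head per task (phase and step).

Causality means output frame `t` reads input frames
`t, t-d, ..., t-(k-1)d` only; the stack's receptive field is
`1 + (k-1)(2^L - 1)` frames (`receptive_field()`), ≈ 34 minutes at 1 fps
for the reference `L = 10, k = 3`.

**Multi-stage refinement.** Stage `s + 1` consumes the *probability* rows of
stage `s`. The study leaves the inter-stage input under multi-task
unspecified; we concatenate both heads' probability rows (width `P + S`,
55 by default), which generalizes single-task probability passing and lets
refinement exploit cross-task consistency. All stages are supervised; the
training loss is the sum over stages and tasks of **unweighted** frame-mean
cross-entropy — deliberately unweighted (unlike the backbone) so the
temporal model learns class durations and transition structure implicitly.
The final stage is the model output.

**Optimization.** Adam (learning rate `3e-4`, the reference value), one
video per optimization step, 200 epochs in the reference recipe; the kept
checkpoint is the epoch with the best validation score (mean of phase and
step frame accuracy). Dropout inside residual layers is 0.5.

**Numerical choices.** All parameters are initialized uniformly in
`±1/sqrt(fan_in)`, the convention of this model family. This matters: a
He-normal (Gaussian, variance `2/fan_in`) initialization grows the residual
activations multiplicatively through deep stacks — at `L = 8` the initial
loss sat two orders of magnitude above `ln P + ln S` and training never
recovered. With the uniform scheme the initial loss starts at the uniform
prediction value and training is stable. The backbone's L2 penalty is
implemented as an additive gradient term (`weight_decay * w`), matching the
classical "weight decay inside the gradient" formulation. Softmax and
cross-entropy are computed with max-shifting and probability flooring at
`1e-300`.

**Streaming.** Every operation is causal, so online inference can be exact.
`tcn_stream()` keeps, per stage and layer, a ring buffer of that layer's
input covering its `(k-1)·d` past taps; memory is bounded by the receptive
field regardless of stream length. `online_predict()` therefore reproduces
the batch forward pass to floating-point noise (measured maximum absolute
probability difference in the shipped acceptance run: `5.6e-17`), and
already-emitted predictions never change when frames are appended.

## Evaluation protocol

`classwise_prf()` computes per-class precision, recall and F1 and their
macro averages; `frame_accuracy()` is the micro average. The annotation
protocol is silent on degenerate cases, which we resolve as:

* a class never predicted but present in the ground truth gets
  precision 0 (never predicting a rare class is not rewarded);
* a class absent from both tracks is excluded from the macro averages
  (impossible classes are not penalized);
* F1 at precision = recall = 0 is 0 (harmonic-mean limit).

`joint_accuracy()` is the fraction of frames with *both* labels correct;
`joint ≥ step − ε` indicates the model has implicitly learned the
phase/step containment. `evaluate_predictions()` defaults to per-video
metrics averaged over videos (matching a protocol that reports per-video
statistics); `granularity = "pooled"` concatenates frames instead.
`make_folds()` reproduces the 40-video / 4-fold layout (test 10 / train 24 /
val 6); `aggregate_folds()` reports mean and *sample* standard deviation.
Ribbon plots (`ribbon_plot()`) render label tracks as colour bands; steps
fold onto a 20-colour categorical map (`id %% 20`) because 44 fully distinct
colours are not distinguishable.

## Synthetic generator: scope and defaults

The study's dataset (40 annotated bypass videos) is private, so all
empirical properties are established on synthetic data. The generator is an
explicit-duration (semi-Markov) model: phases are visited in ontology order,
each skipped with a small probability; a visited phase runs its ordered step
program, each step included with its inclusion probability and dwelling a
truncated-negative-binomial number of frames. Features are class-conditional
Gaussian around per-step mean vectors, optionally with a slow rank-one drift
(lighting/smoke-like appearance change).

`default_model()` emulates the study's scale: expected video length
110 minutes at 1 fps; step dwell means log-spaced over two decades (8–800
frames before rescaling) and shuffled across phases, so the class imbalance
that median-frequency balancing addresses is actually present; negative
binomial dispersion `size = 4`; first step of each phase mandatory, others
included with probability 0.9; phase skip probability 0.05. The generator is
deterministic in `(model, seed)` down to byte-identical on-disk corpora.

What the generator does **not** model: within-phase step reordering or
interleaving, repeated visits to a phase, annotation noise, and any visual
realism — emission is a Gaussian around a class mean, so backbone-quality
questions (what a CNN can extract from real laparoscopic frames) are out of
scope. Claims established here are about the temporal model, the protocol
and the code paths, not about clinical performance.

## Desk-scale acceptance configuration

The shipped acceptance experiment (`scripts/acceptance.R`, mirrored by the
test suite) uses 20 videos of ~600 frames (5 phases / 12 steps, orthogonal
step means in 16 dimensions, emission noise 0.5) and a 1-stage model with
`L = 8`, `C = 32` (receptive field 511 frames, on the order of the video
length) trained 50 epochs at the reference learning rate. This configuration
was fixed before the experiment was run. With seed 1 the held-out results
are phase accuracy 0.980, step accuracy 0.951, joint accuracy 0.947 (means
over 3 derived seeds), and joint accuracy tracks step accuracy to well
within 0.03 — the desk-scale form of the "implicitly learned hierarchy"
property. A single-task step model on the same corpus reaches 0.952, so at
this (easy, fully learnable) desk scale multi-task training neither helps
nor hurts the step task; the study's claimed multi-task *gains* concern the
much harder real-video regime and are not asserted here.

## Limitations

* The small CNN trunk is a contract stand-in, not a ResNet-50; backbone
  numbers at study scale are not reproducible here.
* Training is single-threaded base R; the reference 40-video × 200-epoch
  ×2048-dimensional configuration is runnable but slow on one core. The
  desk-scale defaults in the examples finish in seconds to minutes.
* The generator's linear phase order means phase boundaries are easier than
  in real surgery; absolute synthetic accuracies should not be compared to
  published real-data numbers.
* `residuals()` and `simulate()` methods are not provided for the fitted
  model: frame-wise classification over sequences has no natural residual,
  and data simulation is a first-class module (`sample_workflow()`,
  `emit_features()`) rather than a method of the fit.

```{r example}
# See the README for a complete worked example:
library(surgtcn)
h <- default_hierarchy()
h
receptive_field(n_layers = 10, kernel_size = 3)
```
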