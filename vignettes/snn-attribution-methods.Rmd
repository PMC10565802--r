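---
title: "Attribution for spiking networks: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attribution for spiking networks: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the neuron and network model, the attribution methods, the evaluation
protocols, and the design decisions taken where the design was genuinely
open.

## The spiking substrate

A spiking neural network processes a binary volume of spikes indexed
`(channel, y, x, t)`. Each leaky integrate-and-fire (LIF) neuron keeps a
membrane potential driven by its weighted synaptic input,

$$U(t) = \lambda \, U^{\mathrm{reset}}(t-1) + \textstyle\sum_j w_j\, s_j(t),
\qquad s(t) = \mathbf{1}[\,U(t) \ge \theta\,],$$

with leak factor $\lambda \in (0, 1]$ per timestep, threshold
$\theta > 0$, and a reset applied after each spike — by default the *soft*
reset $U \leftarrow U - \theta$, which loses no super-threshold drive;
the hard reset to zero is available per layer. Time is abstract: one
simulation step is the unit, all time constants are expressed in
timesteps. Within a timestep activity propagates through all layers; the
recurrence couples consecutive timesteps. Networks are composed of
convolutional LIF layers (implemented as sparse weight-tied linear
operators), average-pooling stages (fixed linear maps, no neurons) and
dense LIF layers; the last dense layer has one neuron per class.

The decision rule and the quantity every attribution method explains is
the **class score** $S_C = \sum_t s_C(t)$, the output neuron's spike
count; the winner is the most-spiking output neuron, ties broken toward
the lowest class index (documented and tested).

### Surrogate gradients

The threshold function has no derivative, so backpropagation through time
substitutes a surrogate
$\rho(u) = \tfrac{\alpha}{2} e^{-\alpha |u - \theta|}$ — positive,
maximal at the threshold, symmetric, with sharpness $\alpha$ per layer
(a fast-sigmoid family is available as an alternative). Three gradient
routes are chained per layer and timestep: spike → same-step downstream
input, membrane → next-step membrane through the leak, and spike →
next-step membrane through the reset.

The package's *relaxed* forward mode replaces the hard threshold with the
surrogate's antiderivative (a sigmoid rising through $1/2$ at the
threshold) so that the whole pass becomes smooth and BPTT is its exact
gradient. This gives an independent oracle: central finite differences of
the relaxed pass must match `input_gradient()` to high precision, which
the test suite and the acceptance script verify (observed relative error
around $10^{-8}$, asserted below $10^{-3}$).

### Training

`train_snn()` minimizes the squared error between per-class output spike
counts and targets — the true class is driven toward a high count,
all others toward a low one — with plain SGD. Numerical choices that
matter: gradients of the count loss accumulate over the entire window, so
the default learning rate is small (`2e-4`); larger steps tend to push
layers into silence (no spikes, vanishing surrogate slopes) or
saturation. Weight initialization is scaled-uniform (Glorot bound times a
gain of 3 — spiking layers need somewhat stronger weights than rate
networks for activity to propagate at all), deterministic per seed.
Training is bit-reproducible given the seed, which also drives per-epoch
shuffling.

## Neural encoders

Four codings map an 8-bit grayscale image to spikes. All emit strictly
binary tensors, and all default to a 256-step window so the codings share
a time axis:

* **Time-to-first-spike (TTFS)** — one spike per pixel at $t = v$. The
  *black-earliest* direction is deliberate: the black pixel is the path
  baseline of the integrated-gradients image pipeline, and "encoded
  black" must be the earliest spike for that correspondence to hold. The
  bright-first convention common elsewhere in the latency-coding
  literature is available behind `ttfs_invert`.
* **Poisson (rate)** — independent Bernoulli draws with $p = v/255$ per
  cell; the only stochastic coding, bit-reproducible per seed.
* **Phase** — the 8-bit binary expansion is played out MSB-first over
  each cycle of `phase_period` steps; spikes per period equal the
  popcount of the value. Whether phase significance should also scale
  synaptic efficacy is an open choice in the literature; this
  implementation keeps unit efficacy and leaves weighting to the network.
* **Burst** — $N(v) = \lceil N_{max}\, v/255 \rceil$ spikes from $t = 0$
  at interval $\mathrm{ISI}(v) = \max(1, \lceil (T{-}1)(1 - v/255)\rceil)$.
  Note the count/interval trade-off makes some mid intensities
  *infeasible* (the burst cannot fit the window) for $N_{max} > 2$;
  encoding such a value raises a validation error rather than silently
  clipping. The toy fixtures' intensity palette (30/200/255) is feasible.

`ttfs_decode()` inverts TTFS exactly and is tested over all 256 values.

## Attribution methods

* **SNN-Grad3D** — $\partial S_C / \partial \mathrm{input}$ by surrogate
  BPTT; entry $(c, y, x, t)$ estimates the effect of adding or removing a
  spike there. The default target is the winning class.
* **SNN-IG2D** — integrated gradients for image inputs: a straight path
  of $n$ images from an all-black baseline to the source image, each
  rounded half-up to integers (the encoders consume 8-bit values), each
  encoded and differentiated, gradients averaged. Three deliberate
  choices: the integral is the left-Riemann average of *raw* gradients
  (elementwise scaling by the input-minus-baseline delta is a switch,
  default off, applied at the 2D collapse when requested — enabling the
  classical completeness diagnostic); the target class is fixed to the
  original input's winner across all path steps, so the whole path
  explains one decision; the default $n = 50$ matches the configuration
  the method is conventionally timed at (tests and the acceptance script
  use smaller $n$ for speed, which only coarsens the path integral).
* **SNN-IG3D** — event data is binary, so the path runs along time: from
  the empty stream ("no spike" is the baseline for event data) to the
  full input by sampling timesteps at increasing rate. Two heuristics:
  `stride` (evenly spaced timesteps, default) and `prefix` (leading
  timesteps). Both reduce exactly to SNN-Grad3D at $n = 1$, an identity
  the tests assert to machine precision.
* **SAM / ISAM** — the forward-only spike activation map: per neuron,
  $NCS(t) = \sum_{t' < t,\, s(t')=1} e^{-(t-t')/\gamma}$, channel-summed
  over a convolutional layer's grid ($\gamma = 1$ timestep by default;
  the method is restricted to conv layers by construction). ISAM is the
  exact elementwise negation, ranking least-contributing cells first.
  Layer-resolution maps are upscaled bilinearly (corner-aligned, grid
  values preserved) for superposition on the input image.

Pixel maps come from `collapse_time()` over channel and time — sum by
default, the best-performing of the basic reducers for the gradient
pipelines — and heatmaps are normalized by
$H' = |(H - H_{min})/(H_{max} - H_{min})|$, with the convention that a
constant map normalizes to all zeros.

## Evaluation protocols

**Deletion/insertion.** Features — spike cells or pixels — are ranked by
the map (by absolute or raw score; ties broken lexicographically so the
order is a deterministic total order), then the top fraction $k$ is
deleted (set to the baseline: "no spike" for cells; black/gray/white =
0/128/255 for pixels) or inserted (restored from the baseline), the
network is re-run and mean class-recall accuracy plus the mean spike
count of the originally winning neuron are recorded. "Potential spike
locations" are *all* tensor cells, not just active ones. Evaluation uses
only samples the network classifies correctly, so deletion curves start
at accuracy 1 and attribution maps of wrong predictions never enter. The
control is a seeded uniformly random ranking. Curves are summarized by
trapezoidal AUC: lower is better for deletion, higher for insertion.

**Noise robustness.** Jitter displaces each spike uniformly in
$[-j, +j]$ timesteps (range 0–4 by default), clipped at the window
boundary, colliding spikes merged by OR; deletion noise drops each spike
with probability $p$ (sweep 0–0.9). The metric is *relative accuracy* —
perturbed over clean accuracy on the correctly classified subset, so
level 0 is exactly 1. Noise can be injected at the input or inside the
network: every hidden layer's *delivered* spikes are perturbed each
timestep (the layer's own membrane and reset see its true spikes).
Network-level jitter is delay-only — an online simulation cannot advance
a spike into its own past, so negative draws act as zero delay; this is
the package's causal resolution of an otherwise underdetermined
perturbation and only affects the jitter kind, not deletion.

## The synthetic fixtures and what passing tests show

`make_toy_images()` emulates a class-separable image problem: class $c$
is an oriented bar at angle $180^\circ c / n$ (intensity 200 on
background 30) with salt noise (default rate 0.1), on an 8×8 grid — small
enough that a full 256-step TTFS simulation stays interactive. A
nearest-template oracle classifies this at ≥95%, and the spiking trainer
reaches ≥90% within 20 epochs. `make_toy_event_streams()` emulates an
event camera watching a dot translate in a class-specific direction, ON
events at the new position and OFF at the old (the two-polarity DVS
convention maps to two input channels), plus uniform noise events.

These fixtures are deliberately easy: they validate the *machinery* —
gradients, encodings, protocols, reproducibility — not real-world
performance. They have none of the texture, scale variation or class
overlap of natural images, and the toy networks are orders of magnitude
smaller than deployed SNNs; passing here says the methods are implemented
correctly and behave as the theory predicts on a problem where the
ground truth is visible, not that attribution quality transfers to any
particular real dataset.

The quantitative stand-in experiment (in the acceptance suite) trains the
toy model on **TTFS** coding and checks that deletion AUCs of
SNN-Grad3D(ABS) and SNN-IG3D(ABS) fall below the random control's and
insertion AUCs above it, by sign test over 20 control seeds. TTFS is the
coding under which the reference quantitative protocol operates. A
property worth knowing, observed on the fixtures and left as a documented
limitation rather than engineered away: under *dense rate codings*
(e.g. Poisson), absolute-ranked insertion can lose to the random control —
a uniformly random subsample of spikes preserves firing rates, which is
nearly optimal input reconstruction for a rate-driven classifier, and the
absolute ranking spends its early budget on strongly *negative* cells.
Signed ranking restores the expected ordering there; both modes are
exposed.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run on: 8×8 images, 3
classes, 10 samples per class, T = 256 (TTFS) or 20 (Poisson) timesteps,
networks of ~20–150 neurons, 20 random-control seeds, 8-point fraction
grids, and n = 10 integrated-gradient steps — sizes chosen so the full
suite completes in minutes while every statistical check retains power.
Other conventions: argmax ties go to the lowest index; IG2D path images
round half-up; the feature-ranking tie-break is lexicographic in
coordinates; perturbations always operate on copies (inputs are never
mutated); all stochastic components (Poisson encoder, random control,
jitter, deletion noise, weight init, shuffling) are seeded and
bit-reproducible.

## Known limitations

- Training is plain SGD on the count loss at toy scale; no optimizer
  state, no minibatching, no regularization — adequate for fixtures, not
  a training framework.
- The LIF substrate is the simple discrete-time recurrence; spike-response
  kernels (as in kernel-based training frameworks) are out of scope, as
  the attribution mathematics only requires a differentiable spiking
  forward pass.
- Phase/burst parameterizations follow the canonical published forms with
  parameters exposed in `encoder_config()`; variants exist in the
  literature.
- Network-level jitter is delay-only (causality, above).
- Event-stream ingestion is the plain-text CSV dialect plus in-memory
  records; binary camera-vendor formats are intentionally unsupported.
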