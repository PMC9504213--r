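---
title: "Continual prototype learning on sensor streams: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continual prototype learning on sensor streams: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `protostream`,
the knobs that matter, the choices made where the design was genuinely open,
and what the package's synthetic experiments do and do not demonstrate.

## Model and assumptions

The framework treats activity recognition as *task-free data-incremental
learning*: labelled windows arrive in small batches with no task boundaries,
mixing previously seen and novel activity classes in non-i.i.d. proportions,
and each training batch is seen exactly once. Three assumptions are built
in: (i) windows arrive already labelled (activity discovery and label
acquisition are out of scope); (ii) window length and channel count are
fixed across the stream; (iii) the class inventory only grows — prototypes
are never aged out.

The learner has three coupled state components:

* **Encoder** `f_θ` — stacked valid, stride-1 temporal convolutions
  (channels as input feature maps) followed by stacked LSTMs; the embedding
  is the final-timestep hidden state of the last LSTM layer. Which LSTM
  output to use is a genuine choice; the final hidden state is the standard
  classification read-out for this architecture family and keeps the
  embedding dimension equal to `lstm_hidden`. Parameter count is independent
  of the number of classes: all class knowledge lives in the prototypes.
* **Prototype memory** — one vector per seen class with a running count.
  Known classes are refined by *exact* online averaging, so any partition of
  a class's windows yields the same prototype as one batch mean under a
  fixed encoder (this equivalence is tested to 1e-6). The adaptation rule
  `p ← α·p + (1−α)·mean(replay)` with `α = c/(c+m)` and the incoming batch
  as the replay set reproduces the online-averaging update exactly — the
  fixed-α form trades that exactness for a stabilised trajectory in the
  moving embedding space.
* **Replay buffer** — raw windows (never embeddings), so exemplars can be
  re-embedded under any later encoder; uniform without-replacement
  resampling per class, deliberately avoiding herding-style selection.

Two details fix the semantics of a step. First, memory refinement runs under
the *pre-step* encoder while adaptation runs under the *post-step* encoder —
refinement incorporates the batch as the model saw it, adaptation re-anchors
prototypes to the space the model just moved to. Second, prototypes are
treated as constants in the streaming loss (no gradient flows from the
cross-entropy into the memory); during episodic pretraining the episode
prototypes *are* differentiated through, since there they are formed from
the support embeddings inside the same computation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lstm_hidden` (d) | 128 | embedding dimension; reduced to 32 in the package's own experiments |
| `learning_rate` | 0.001 | Adam step size for both pretraining and streaming |
| `margin` (m) | 1 | minimum embedding distance enforced between classes (same units as embedding distance) |
| `alpha` (α) | 0.5 | refresh ratio; 1 keeps old prototypes, 0 snaps to the replay mean |
| `buffer_capacity` (b) | 6 | stored windows per class |
| `stream_batch_size` | 20 | windows per stream step |
| `max_classes_per_batch` | 5 | non-i.i.d. constraint on each batch |
| `n_base`, `pretrain_fraction` | 5, 0.5 | base classes and the share of their training windows used offline |
| `epochs` | 100 | episodic pretraining episodes (× `episodes_per_epoch`) |

The margin and refresh ratio are the two scientifically interesting dials —
`run_sweep()` reproduces the margin grid {0.2, 1, 2, 3} and an α grid over
[0, 1] as one-line experiments.

## Numerical and procedural choices

* **Distance.** The classification softmax uses squared Euclidean distance
  (the prototypical-network convention); plain Euclidean is selectable and
  provably yields identical argmax predictions.
* **Contrastive form.** The dissimilar-pair penalty is the classic
  `max(0, m − d)²` (margin against *distance*), with the variant
  `max(0, m − d²)` selectable; the classic form gives the margin its usual
  length units, matching the margin grid above. The reduction over pairs is
  the mean, keeping the loss scale batch-size independent.
* **Optimiser.** Adam, with zero gradient producing exactly zero update, so
  a zero loss leaves parameters untouched; non-finite losses abort the step.
  The update consumes analytic gradients (backprop through the LSTM and
  convolution stack, verified against finite differences in the tests).
* **Ties and degenerate inputs.** Distance ties in classification break
  towards the smallest class id (determinism). A window label under
  sliding-window segmentation is the majority per-sample label, ties to the
  last timestep. A pretraining class with one window in an episode batch
  contributes support only; a class with one window overall is an error.
  Forgetting of a class whose historical best is 0 is defined as 0, and the
  measure is floored at 0 so an improving class reports "no forgetting"
  rather than a negative value; intransigence, by contrast, is a signed gap.
* **Episodes.** Support/query splits are 50/50 per class within each
  sampled episode batch, one episode per epoch by default
  (`episodes_per_epoch` raises the gradient-step budget without changing
  the schedule's meaning).
* **Randomness.** Every run expands one master seed into named sub-streams
  (split, schedule, initialisation, buffer, augmentation), so components can
  be perturbed independently and buffer contents are reproducible regardless
  of ambient RNG use.
* **Batch expansion.** "Four augmentations" is read as original + four
  augmented copies (5n windows): jitter, per-window scaling, spline-based
  time warping and magnitude warping, each degenerating to the identity as
  its parameter vanishes.

## The synthetic generator

`generate_stream_data()` emulates the structure the method's claims depend
on: class-conditional multichannel archetypes (sinusoid mixtures or
band-limited noise) with additive Gaussian noise, class imbalance via
per-class counts, *confusable pairs* whose archetypes differ by a
perturbation shrinking with `class_separation` (activities with
near-identical sensor patterns), and the ≤5-classes-per-batch non-i.i.d.
schedule. Difficulty is governed by `class_separation / noise_sigma`.

What it does **not** emulate: sensor drift and concept drift within a class,
heteroscedastic and correlated sensor noise, label noise, subject-to-subject
variability, and the heavy-tailed class imbalance of real deployments.
Passing tests therefore demonstrate the *mechanism* — that replay,
adaptation and the contrastive term preserve base-class performance and
accelerate new-class learning relative to online finetuning under controlled
conditions — not performance levels on any real dataset. Real data enters
through `read_dataset()` (flattened-window CSV or raw delimited signals plus
a YAML format descriptor) with dataset-specific channel selections expressed
in the descriptor, never hard-coded.

## Problem sizes used by the package's experiments

The test suite runs a reduced encoder (2 convolutional layers, 16 filters,
1 LSTM layer, 32 hidden units) on streams of 6-10 classes with 18-60 windows
per class; the end-to-end comparison uses 10 classes (5 base), moderate
separation (5 vs noise 1), 5 seeded runs per mode, and 30 pretraining
episodes. `scripts/acceptance.R` uses the same conditions with the standard
100-epoch pretraining budget and 3 runs per mode. These sizes are the
package's own choices for a self-contained, repeatable experiment; the
framework itself scales to the full architecture defaults.

## Known limitations

* The encoder trains on CPU via plain matrix algebra; it is sized for
  research-scale windows (tens of channels × tens of timesteps), not for
  113-channel, high-rate streams at production scale.
* The intransigence reference is itself a trained model; with few training
  episodes it can understate the achievable upper bound, making
  intransigence look benign. Negative intransigence is possible and is
  reported as such.
* Mode `adapt_only` keeps maintaining the replay buffer (adaptation needs
  it) while excluding replayed windows from the loss; interpretations that
  drop the buffer entirely would also disable adaptation and are not
  implemented.
* No activity discovery, active labelling, prototype aging or
  update-gating; these are deliberate non-goals of the present scope.
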