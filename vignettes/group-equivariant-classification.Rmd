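---
title: "Group-equivariant classification of rotation-invariant microscopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-equivariant classification of rotation-invariant microscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equivnet)
```

## The model

Microscopy classification tasks are frequently invariant to the global
orientation of the sample: a rotated virus particle is the same particle.
`equivnet` builds this symmetry into the classifier rather than into the
data. The two groups supported are p4 — quarter-turn rotations, order 4 —
and p4m, which adds a reflection, order 8. On square pixel grids these act
by exact index permutations (flip/transpose compositions), so every layer
property below holds *exactly*, not approximately.

A group element is a pair `(mirror, rotation)` acting mirror-first.
Rotation is counterclockwise; the reflection is a left-right flip. Neither
choice is forced by the mathematics — both orientations of each convention
produce isomorphic groups — but one pair must be fixed, and the derived
composition table (computed at group construction by acting on an
asymmetric probe array) is the single source of truth used by every
downstream operation, so all code is convention-consistent by
construction. Even-sized arrays rotate about the array centre, which the
flip/transpose realization gives for free.

Three operators make up the equivariant network:

* **Lifting convolution** (`lift_conv`): correlates a planar input with
  every group-transformed copy of the kernel stack, producing a feature
  map indexed by `(channel, group element, row, column)`.
* **Group convolution** (`group_conv`): maps group stacks to group
  stacks; the output slice at element `g` sums over input elements `h`
  the correlation of the `h`-slice with the kernel slice indexed
  `g^{-1}h`, spatially transformed by `g`. Source material for this layer
  family typically states only the input-layer formula; the
  layer-to-layer form used here is the standard regular-representation
  construction, and the binding contract is the equivariance identity
  itself, which the test suite checks exhaustively over group elements.
* **Group pooling** (`group_pool`): per-pixel max over the group axis,
  converting equivariance into invariance; after the final global spatial
  pool the logits are invariant to any group transformation of the input.

Implementation strategy: *kernel expansion*. All transformed kernel copies
are precomputed as index permutations of the stored weights and dispatched
to one compiled planar-correlation primitive (im2col plus BLAS
matrix multiply); gradients are scattered back through the same index map,
so weights remain shared across the group axis during training, as does
the per-channel bias. The correlation-vs-convolution bookkeeping (deep
learning's "convolution" is a correlation) is absorbed into the
transformation index maps and pinned down by independent nested-loop
oracles in the test suite rather than by convention arguments.

## Architectures and parameter parity

`arch_config()` describes a VGG16-style classifier once; the baseline and
equivariant variants derive from the same description. The full-scale
defaults are thirteen convolutions (channels
32-32-64-64-128-128-128-256-…-256, spec (3,1,1) except a final (4,1,0)),
max pools after layers 2, 4, 7, 10, 13 (four (2,2,0), one global (13,1,0)),
two 4096-wide hidden linear layers with dropout 0.5, and He-initialized
weights. Two printed-schedule ambiguities had to be resolved: a conv
stride of 0 is impossible, so layer 13's "(4,0,0)" is read as kernel 4,
stride 1, padding 0 — the only reading that produces the 13×13 input the
final pool expects — and pool placement follows the canonical VGG16
positions, the unique placement consistent with a 256×256 input reaching
a 1×1 flatten of width 256.

For the equivariant variant every channel count is divided by
`channel_divisor` (default 2). On p4 this gives exact weight parity per
group-to-group layer: `(c_out/2) · (c_in/2 · 4) · k² = c_out · c_in · k²`.
The lifting layer (no group axis on its input) then carries half the
baseline weights, and the first linear layer shrinks because group pooling
halves the flattened width (128 vs 256 at full scale) — the hidden linear
widths themselves are not halved. The total parameter ratio is therefore
slightly below one; it is reported by `count_parameters`, not asserted. On
p4m the same divisor leaves group layers at twice the baseline count (the
group order is 8); the divisor is configurable and the package does not
claim parity there. He fan-in for group layers includes the group axis
(`c_in · |G| · k²`); dropout sits after each hidden linear layer; there is
no batch normalization.

## The synthetic data generator

Real TEM virus or stained blood-cell collections are not shipped with the
package; `generate_dataset()` emulates their decisive statistical
property — classes distinguished by rotation-invariant morphology, each
sample observed at an arbitrary global orientation. A class template is a
centred bright ring (envelope) with an optional corona of radially
arranged protrusions and a radial internal texture; the default palette
varies spike count (mostly non-multiples of four, so appearance genuinely
depends on orientation), radius, texture frequency and intensity. A sample
is its template transformed by a random p4 element (exact, the default) or
a random continuous angle (bilinear interpolation, flagged, and excluded
from exact-equivariance claims), shifted by integer jitter, plus additive
Gaussian noise clipped to `[0, 1]`.

What this does *not* emulate: detector physics, stain variability, contrast
transfer, debris, within-class shape heterogeneity, or scale variation.
Passing tests on this generator demonstrate that the operators and the
experimental machinery behave as specified under the symmetry the model
targets — they do not certify accuracy figures on real micrographs.

The surrounding procedures mirror a realistic pipeline: `augment_p4m`
expands each training image to its eight-element orbit; `rebalance`
downsamples every class to the smallest *original* class count, removing
augmented copies first and then originals at random (so augmenting an
already-balanced set and rebalancing returns exactly the originals);
`subsample_training` draws class-balanced nested subsets (prefixes of one
seeded permutation, so smaller training sets are contained in larger ones
across a scaling sweep); `make_cv_folds` builds class-stratified folds in
two modes — `"even"` partitions each class into sizes differing by at most
one, while `"fixed"` holds exactly `test_size` per class in each test fold
and leaves any remainder permanently in training (with 123 per class, five
folds and `test_size = 23` this yields the classic 100-train / 23-test
per-class split).

## Training and convergence metrics

`train_classifier` runs plain minibatch Adam on cross-entropy for exactly
`n_epochs` — no early stopping, schedule, or weight decay — recording per
epoch the training loss, validation accuracy and cumulative wall-clock
time. The full-scale reference recipe (learning rate 1e-5, 100 epochs) is
the default `training_config()`. Batch size is not part of that recipe;
32 is the package default. Adam's moment parameters are the conventional
0.9/0.999/1e-8. With a fixed seed and single-threaded BLAS the loss
sequence is reproducible on one machine.

The convergence summary (`stability_metrics`) is: top accuracy = maximum
validation accuracy over the run; stable epoch = first epoch reaching at
least 95% (configurable) of that maximum, with ties resolved by the
"at least" comparison; stable accuracy and time-until-stability read off
at that epoch. Wall-clock times are recorded but hardware-dependent, so
package tests assert only epoch-indexed quantities.

## Evaluation and data-efficiency fits

`confusion_matrix` (rows actual, columns predicted) feeds one-vs-rest
macro sensitivity and specificity — unweighted class means, the reading
adopted where a source says only "average"; micro-averaged variants are
provided alongside. `fit_power_law` fits `y = a·x^k` by ordinary least
squares of `log y` on `log x` (via `lm`; natural logs, slope
base-invariant). `run_scaling_experiment` measures the end error
(1 − final-epoch accuracy by default; best-epoch configurable, since
either reading is defensible) on a fixed held-out set across nested
training subsets and fits one power law per model family to the per-size
mean errors. `run_main_experiment` executes the 2×2 protocol — baseline
and equivariant, with and without orbit augmentation — over a seed list,
with an equivariance self-check before any training, and summarizes the
three planned contrasts with relative improvements in percent.

## Numerical choices and problem sizes

* Equivariance tolerances: exact equality for integer-valued inputs and
  weights (all arithmetic is double-precision and index permutations are
  exact); 1e-4 absolute for end-to-end logits on random real inputs;
  an empirical checker (`check_equivariance`) reports per-element
  deviations for any layer function.
* Zero padding everywhere; borders break exact translation equivariance,
  but not quarter-turn equivariance of square inputs, which is the tested
  property. Pooling windows use no padding.
* Group-pool ties (two group slices attaining the max) route gradients to
  the first attaining slice, matching the forward argmax.
* Desk-scale study conditions, used by the directional experiment in the
  test suite and acceptance script: 4 classes, 64×64 images, 32 training
  and 25 validation images per class, noise sd 0.1, jitter 2 px, 20
  epochs, Adam at 1e-3, batch 16, three seeds per condition. The compact
  preset (channels 8-8-16-16-32) keeps the full architecture's structure
  at a fraction of its width — wide enough that halving the equivariant
  variant's channels does not starve its first layers, which at very
  small widths dominates any symmetry effect. The learning rate is raised
  from the full-scale 1e-5 because at twenty epochs that schedule cannot
  leave the chance plateau, and kept at the conventional 1e-3 rather than
  higher values at which individual runs of the deeper effective stack
  train erratically. Mean top validation accuracies and their margin are
  reported; the package asserts only the direction (equivariant ≥
  baseline without augmentation), which is the property the symmetry
  argument predicts.
* Replication is three seeds per condition (a five-seed protocol is the
  full-scale convention; three keeps the desk experiment brief while
  still averaging over initialization and shuffling noise).

## Known limitations

Only the two quarter-turn point groups are provided — no finer angular
resolutions, steerable bases, or 3-D groups. The continuous orientation
mode interpolates and therefore sits outside all exactness guarantees.
The training engine is a minimal CPU implementation intended for
desk-scale study, not a competitor to GPU frameworks; full-scale runs of
the 256×256 architecture are out of its intended envelope. Wall-clock
convergence comparisons depend on hardware and are reported without
assertion.
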