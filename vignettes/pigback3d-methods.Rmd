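---
title: "Individual pig identification from overhead back-surface point clouds: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual pig identification from overhead back-surface point clouds: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pigback3d)
```

## The problem

Precision livestock farming needs to know *which* animal a sensor is
looking at before any per-animal monitoring (feeding, weight, health) is
possible. Ear tags are invasive and lossy; 2D face or coat recognition
struggles with pigs, whose faces are hard to image frontally and whose
bodies are uniformly coloured and often dirty. An overhead depth camera
sidesteps all of this: the 3D surface of a standing pig's back encodes
its body widths, heights, length and individual surface relief, and is
insensitive to lighting and dirt.

`pigback3d` implements a two-stage pipeline on raw overhead scans:

1. **Segmentation** — a hierarchical point-cloud network labels every
   point *back* or *background* (ground and head are both background;
   the head is excluded from the target because its pose and
   completeness vary between frames).
2. **Identification** — the retained back points are resampled to a
   fixed size, normalized to the unit ball, and classified into one of
   K known individuals.

Both stages operate directly on unordered point sets. No hand-crafted
features, no surface reconstruction, no denoising: the segmented cloud
goes straight into the classifier.

## Models

### Shared building blocks

A *set-abstraction* (SA) level compresses a cloud: farthest point
sampling (FPS) selects `m` well-spread centroids; a *ball query*
collects up to `cap` neighbours within radius `r` of each centroid (in
ascending input-index order, padded by repeating the first member; an
empty ball falls back to the nearest point); each neighbourhood is
expressed in coordinates relative to its centroid, pushed through a
shared MLP, and max-pooled. Max-pooling makes the feature exactly
invariant to member order and to duplicated members.

The segmentation model is an encoder–decoder: two SA levels down, then
two *feature propagation* stages back up, each interpolating coarse
features onto finer points by inverse-distance-squared weighting over
the k = 3 nearest coarse points (a coincident point receives its coarse
feature exactly — the d → 0 limit), concatenating skip features, and
applying a stage MLP. A per-point head emits two log-probabilities.

The classifier drops the decoder: two SA levels, a final MLP over the
surviving centroids (coordinates + features), a global max-pool, and a
fully-connected head with log-softmax output.

### Grouping strategies

* **SSG** — one radius per SA level (0.2, then 0.4, in unit-ball
  units).
* **MSG** — three radii per level (0.1/0.2/0.4 and 0.2/0.4/0.8), their
  pooled features concatenated, which buffers the non-uniform density
  that random resampling produces.
* **LGG** — MSG plus a fourth, *adaptive global* branch per level. Its
  radius is `Rfst`, the farthest pairwise distance among that level's
  own FPS centroids, recomputed per sample and per level, so each
  centroid also aggregates a whole-object neighbourhood that scales
  itself to the sample at hand. At full scale the LGG classifier has 9
  MLP blocks (4 branch MLPs per level + the final one) and widens the
  final global feature to 2048.

`Rfst` is interpreted as the *maximum pairwise distance* among the
sampled centroids, not the last FPS increment: the global ball is meant
to cover the whole sampled set, and only the max-pairwise reading
guarantees that (the centroid pair realizing `Rfst` then lie in each
other's global neighbourhood). For unit-ball input `Rfst <= 2`, and it
is always between half and one cloud diameter.

### Full-scale vs. desk-scale geometry

`scale = "full"` reproduces the published geometry: 2500 input points,
512 and 128 centroids, MSG level-2 feature width 640 (643 with the
centroid coordinates), LGG final feature 1 × 2048, K = 10 output
classes. These dimensions are pinned by tests but are too heavy to
*train* routinely on one CPU.

`scale = "small"` is the package's desk-scale geometry for 600-point
clouds: 128 and 32 centroids, branch widths an eighth of the full ones,
LGG global MLP of two layers ending at 384 features. The choices were
made once, while designing the scaled study, with the criterion that
every variant optimizes stably within the study's 30-epoch budget: a
three-layer global MLP, 64/16 centroids, or head dropout each left some
variants stuck predicting the uniform distribution for the whole
budget.

## Training

Negative log-likelihood on log-softmax outputs, Adam, batch size 8,
best-validation-epoch checkpointing, no early stopping. The package
default learning rate is 0.001. Every training pass draws a *fresh*
random fixed-size resample of each scene (the resampling is part of the
dynamic augmentation), normalizes it to the unit ball, and — when
augmentation is on (the default) — applies a random rotation about the
vertical axis and i.i.d. Gaussian jitter of sd 0.02 in unit-ball units.

Three departures from naive defaults matter at desk scale and are
applied uniformly to all variants:

* **Variance-calibrated initialization.** After fan-in uniform init,
  each linear layer is rescaled (sequentially, re-running the forward
  pass between layers) so its output has unit standard deviation on a
  few probe clouds. Branches with radii from 0.1 to the global `Rfst`
  otherwise produce features on scales an order of magnitude apart, and
  the concatenation starves the small-radius branches. An optional
  per-channel normalization layer (`norm` in the configs) exists as an
  alternative but removes per-sample location/scale information, which
  at desk scale is a large part of the identity signal, so it is off by
  default.
* **Absolute coordinates as level-1 features.** Each level-1
  neighbourhood sees both relative and absolute member coordinates, as
  in the canonical implementations of this architecture family.
* **Learning-rate warmup and gradient clipping** are available
  (`warmup`, `clip`) but off by default.

## The synthetic scan generator

No public dataset of overhead pig scans exists, so the package
generates its own and treats the generator as first-class, tested
code. A scene is:

* a square **ground plane** at height 0 (uniform points at
  `point_density` per m²);
* the **back shell**: cross-sections are superellipse arcs (exponent
  2.5 — flat-topped, round-shouldered) whose half-width interpolates
  chest to hip width and whose apex height interpolates chest to hip
  height along the spine; bundled measurements for ten ~60–90 kg
  crossbred pigs drive it (pigs 1/2/6/7, 3/4/5 and 8/9/10 form
  similar-size groups);
* an optional **head**: a half-ellipsoid cap at the chest end, labelled
  background like the ground;
* the **occlusion shadow**: all ground points inside the animal's
  vertical footprint are removed, exactly as an overhead depth sensor
  sees it — this point-free band is what makes the back silhouette
  segmentable;
* **cracks**: `crack_count` thin stripes (1–2 cm) deleted along the
  high-curvature ridge, emulating structured-light dropouts;
* **sensor noise**: i.i.d. Gaussian displacement (default sd 3 mm,
  typical for consumer depth cameras at ~2.5 m);
* **per-identity surface relief**: a bounded low-order harmonic height
  modulation (default amplitude 2% of local height) whose coefficients
  are a deterministic function of the identity. Five tape-measure
  lengths alone leave same-breed pigs as near scale-copies of one
  another, and the pipeline's unit-ball normalization then removes
  almost all identity signal — while real pigs of one breed are
  demonstrably separable from surface shape alone. The relief stands in
  for the idiosyncratic muscle/fat distribution that real scans carry.
  It is the one generator feature with no direct physical measurement
  behind it, and its amplitude is the honest knob that controls task
  difficulty.

Pose jitter in datasets: rotation uniform in ±15° about the vertical
axis and translation uniform in ±0.1 m per horizontal axis — enough to
decorrelate frames while keeping the animal in frame. Splits are
stratified 3:1 train:validation per identity. Everything is
deterministic under the scene seed.

What the generator does **not** emulate: posture variation (arched or
lowered backs), multiple animals per frame, pen furniture, motion blur,
or realistic depth-sensor noise structure (axial noise growth,
edge artifacts beyond the deleted cracks). Passing tests on synthetic
scenes therefore demonstrate that the pipeline's machinery works and
that its comparative statements hold under controlled conditions — not
that the absolute accuracies transfer to a real barn.

## The desk-scale study

The bundled study (run by `scripts/acceptance.R` and mirrored in the
test suite) uses 4 pigs with the bundled measurements forming two
similar pairs (pigs 1/2 and 4/5), 40 frames each (120 train / 40
validation), 600-point clouds, relief amplitude 0.035, and 30 training
epochs — sizes chosen so the whole study runs in minutes on one CPU.
Two study-specific choices, each applied identically to every variant:

* **Augmentation off for identification.** The scenes already randomize
  pose within the range an overhead camera sees; with full-rotation
  augmentation none of the variants leaves the uniform-prediction
  plateau within 30 epochs (learning rotation-invariant features from
  120 clouds needs far more steps). Segmentation, with its dense
  per-point supervision, trains fine with augmentation on and keeps it.
* **Learning rate 5e-4.** At 15 optimizer steps per epoch, the 0.001
  default makes the four-branch variants churn without converging; half
  that rate lets every variant train. The package default remains
  0.001.

Typical results at these sizes: back-segmentation overall accuracy
≥ 0.99 on held-out frames, and mean identification accuracy ordered
LGG > MSG > SSG > PointNet — the same ordering as the full-scale
published comparison, at much lower absolute accuracy (tens of minutes
of CPU training on 120 clouds versus GPU-days on thousands of frames).
Identification accuracies at this scale have large seed-to-seed spread;
the study therefore reports means over three seeds and the per-seed
LGG ≥ SSG fraction rather than any single number.

## Numerical and interface choices

* Depth → cloud: `x = D(x'-cx)/fx`, `y = D(y'-cy)/fy`, `z = D`, pixel
  indices corner-origin, principal point (cx, cy) defaulting to 0 so the
  plain projection model is the default; depth quantized to integer
  sensor units (1 mm default) with 0 = invalid.
* Duplicate frames: adjacent frames with equal point counts are
  duplicates; the first of each run is kept.
* Ball-query padding repeats the first found index; an empty ball
  repeats the nearest point. FPS starts at index 1 by default
  (overridable, or `"random"`); ties break to the lowest index. Because
  a truncating ball query keeps the *first* members in input order,
  classification is exactly permutation invariant (with the FPS start
  pinned to a fixed point) only when caps do not truncate; padding
  duplicates never change a max-pooled feature.
* `identify_pig()` canonicalizes the vertical axis by the sign of the
  z-skewness, so camera-frame clouds (depth growing toward the floor)
  and world-frame scenes (height growing away from it) are equivalent
  after normalization.
* Max-pool gradients route to the first maximizing row; padded
  duplicates are copies of one upstream quantity, so this equals the
  smooth derivative (verified against numeric differentiation to 1e-4).
* Metrics: confusion rows are true labels, columns predictions;
  per-class IoU = TP/(TP+FP+FN); mIoU is their mean; overall
  precision/recall/F1 are macro averages while overall accuracy is
  micro; 0/0 ratios report 0 and set the `undefined` flag.
* Segmentation of clouds larger than the training size tiles them with
  random subsets, preferring unlabelled points, and majority-votes per
  point. Identification refuses to classify when fewer than a tenth of
  the classifier's input size survives segmentation (`no_animal`
  error) instead of forcing a label.
* Checkpoints and dataset archives use R's native serialization
  (`save_model`/`load_model`, `save_dataset`/`load_dataset`); clouds
  exchange as PLY/PCD with an integer `label` property, depth frames as
  16-bit PGM, rosters as JSON.

## Known limitations

* The networks are trained on CPU in R; full-scale (2500-point,
  150-epoch) training is architecturally supported but practically
  slow. The full-scale configurations are exercised as forward passes.
* The desk-scale identification accuracies are not comparable to the
  published full-scale numbers and are not meant to be; only the
  internal metric arithmetic of the published tables and the
  directional model ordering are reproduced.
* One published table cell is internally inconsistent (a total-F1 value
  that does not equal the F1 of its own printed precision/recall); only
  internally consistent cells are asserted.
* Single-animal scenes only; the segmenter labels one connected back
  region and the pipeline assumes at most one pig per frame.
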