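# pigback3d

Individual identification of fattening pigs from overhead 3D scans of
their back surface, in two stages:

1. a hierarchical point-cloud **segmentation** model (set abstraction by
   farthest point sampling + ball-query grouping, feature propagation by
   inverse-distance-squared interpolation) separates the animal's back
   from ground and head;
2. a point-cloud **classifier** assigns the individual identity. Besides
   the single-scale (SSG) and multi-scale (MSG) grouping baselines and a
   flat PointNet baseline, the package implements **local-global
   grouping (LGG)**: each set-abstraction level augments its local radii
   (r1, r2, r3) with an adaptive global radius `Rfst` — the farthest
   pairwise distance among that level's own sampled centroids,
   recomputed per sample — so every centroid also aggregates a
   whole-object neighbourhood:

   f(x_i1..x_im) = [ f_r1 | f_r2 | f_r3 | f_Rfst ],
   f_r = max-pool over the r-ball of a shared MLP on relative coordinates.

Because no public overhead-scan dataset of pigs exists, the package
ships a tested synthetic scene generator (parametric back shell over a
ground plane with occlusion shadow, head, sensor noise, ridge cracks
and per-identity surface relief) plus depth-frame conversion under the
pinhole model, PLY/PCD/PGM IO, training with Adam on a negative
log-likelihood loss, and confusion-matrix metrics (accuracy, precision,
recall, F1, IoU, mIoU). The neural networks, including the backward
pass, are implemented in the package (R with Rcpp kernels) and verified
against numeric gradients.

## Worked example

```r
library(pigback3d)

# 1. simulate a small two-animal farm: 12 frames each, 3:1 split
roster <- pig_roster(c(1, 10))              # two dissimilar pigs
ds <- make_dataset(roster, 12, scene_config(seed = 77, point_density = 1500,
                                            surface_detail = 0.035))
ds
#> scan_dataset: 24 scenes, 2 identities (18 train / 6 val)

# 2. train both stages (desk-scale geometry)
seg <- fit_pointnetpp(ds, "segmentation", npoints = 400, epochs = 40,
                      seed = 5, augment = FALSE)
cls <- fit_pointnetpp(ds, "classification", "ssg", npoints = 400,
                      epochs = 30, seed = 5, augment = FALSE, lr = 5e-4)
cls
#> pointnetpp_fit: classification (ssg), 2 classes, 400 input points
#>   trained 30 epochs (batch 8, lr 0.0005), best epoch 13, val accuracy 0.8333

# 3. identify the animal in a held-out scene (true identity: 0)
sc <- ds$scenes[[which(ds$split == 1)[1]]]
identify_pig(sc$cloud, seg, cls, seed = 11)
#> identified individual: class 0 (p = 0.573), 452 back points
```

The identification result carries the K class probabilities, the
retained back-point count and a provenance block (input, seed, model
hashes). `identify_pig()` runs the full pipeline: segment every point, keep the
back points (never the background), resample to the classifier's input
size, normalize to the unit ball, classify. A ground-only scene raises
a `no_animal` error instead of a forced label.

Evaluation mirrors the published table layout:

```r
ev <- evaluate_model(cls, ds, "val")
ev$metrics
#> accuracy 0.8333 | mIoU 0.7083 | macro P 0.8750 R 0.8333 F1 0.8286 (n = 6)
ev$confusion            # rows = true identity, columns = predicted
#>     pred
#> true 0 1
#>    0 3 0
#>    1 1 2
```

At these toy sizes (24 scenes, 30 epochs, CPU-minutes of training) the
numbers are modest by design; the desk-scale study below and the
methods vignette discuss what scales with more data and training.

A thin command-line front end with the same verbs (`simulate`,
`convert`, `train-seg`, `train-cls`, `eval`, `identify`) is installed at
`inst/cli/pigback3d.R`.

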