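---
title: "Methods: texture-based profiling of DNA damage in 3D histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based profiling of DNA damage in 3D histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thick (~125 µm) cleared tumor sections imaged by confocal microscopy give
3D multi-channel volumes in which DNA damage state is read out from the
γH2AX channel: phosphorylated H2AX accumulates at double-strand breaks,
producing discrete nuclear foci during active repair and near-uniform
pan-nuclear staining in heavily damaged or apoptotic cells. Rather than
counting foci, this package profiles the *staining texture* of each
γH2AX-positive nucleus, clusters cells into pseudo texture classes, and
summarizes how those classes co-occur in local cell neighborhoods — and
how close cytotoxic (CD8+) T cells sit to damaged cells — so that control
and treated tissue regions can be compared quantitatively.

The nuclei instance segmentation is an *input* (any external segmenter,
e.g. a pre-trained Cellpose model on the DAPI channel, produces the label
volume); this package starts where that segmentation ends.

## Coordinate and unit conventions

All volumes are `(z, y, x)` arrays. Distances and radii are quoted in
*lateral pixels*; the default lateral pitch of 0.32125 µm/px (so 32 px =
10.28 µm, 64 px = 20.56 µm, 128 px = 41.12 µm) is attached to every
volume and propagates into all µm-denominated outputs. The z step of a
stack is acquisition-dependent and configurable; when it differs from the
lateral pitch, z-axis differences are rescaled by the anisotropy factor
before any distance is computed, which keeps "radius in px" statements
meaningful on anisotropic stacks. Bounding boxes are 0-based and
half-open.

## Marker-positive cell identification

A marker channel is thresholded (global Otsu over the intensity histogram
by default; a fixed threshold is available and is required for
degenerate, constant channels) and superimposed on the instance
segmentation. For each nucleus,

overlap = |instance ∩ mask| / |instance|,

and the cell is called positive when the overlap reaches a threshold.
Two marker-specific defaults:

* **γH2AX** (nuclear): no dilation, majority overlap (0.5). "Significant
  overlap" is not quantified in general; majority overlap is the natural
  default and the threshold is exposed for sensitivity analysis.
* **CD8** (membrane-bound): the instance is first dilated by a 2-voxel
  ball, and the default threshold is 0.15. A membrane marker can only
  ever occupy the outer band of the dilated nucleus — roughly
  1 − (r/(r+d))³ of it, under half for larger nuclei — so majority
  overlap is geometrically unattainable and a band-sized threshold is the
  meaningful default. Both the radius and the threshold are configurable.

Dilation is implemented as an offset sweep ordered by distance, so grown
instances never merge: a contested voxel goes to the nearest original
instance (ties resolved deterministically by sweep order).

## Texture representations

Each γH2AX+ nucleus contributes one 64×64 patch: the central z-slice of
its bounding box, with voxels outside the instance zeroed (so neighboring
nuclei cannot leak into the texture; flag `mask_background`), padded
centered onto the canvas (isotropically downscaled first if larger), and
min–max scaled to [0, 1]. A constant canvas maps to all zeros. 2D patches
are used because the latent-representation branch consumes 64×64 images;
whether small nuclei should be rescaled rather than padded is genuinely
open — padding preserves foci scale, so it is the default for
smaller-than-canvas nuclei.

### GLCM branch

The gray-level co-occurrence matrix counts pairs of quantized intensities
at fixed pixel offsets. Defaults: 32 gray levels (enough to resolve foci
contrast on 64×64 patches without starving the counts), distance 1, the
standard 4-angle set {0°, 45°, 90°, 135°}, symmetrized and normalized,
averaged over offsets — which makes the averaged matrix exactly invariant
to 90° patch rotations. Four Haralick-style features summarize p(i, j)
(0-based levels, marginal means μ and SDs σ):

* energy = Σ p², contrast = Σ (i−j)² p,
* cluster prominence = Σ (i+j−μᵢ−μⱼ)⁴ p,
* correlation = Σ (i−μᵢ)(j−μⱼ) p / (σᵢσⱼ), defined as 1 when σᵢσⱼ = 0
  (a constant image is perfectly correlated — a convention, therefore
  documented).

Background zeros participate in the counting (they are the background
gray level); excluding background-touching pairs is available behind a
flag. The feature set is implemented against an independent double-loop
oracle in the test suite (agreement to 1e−10).

### VAE-GAN branch

A variational autoencoder with an adversarial discriminator provides
learned 16-dimensional representations. Architecture facts that are fixed
by design: encoder = 3 stride-2 conv layers with batch normalization
followed by dense layers emitting (μ, log σ²); generator mirrors it with
3 transposed conv layers and a sigmoid output; discriminator = 5 conv
layers with batch normalization, with feature maps tapped after the 4th
layer defining the learned similarity metric; latent dimension 16; Adam
at learning rate 1e-4 for all modules; the reference schedule is 500
epochs. Free implementation choices, all configurable: 4×4 kernels,
stride 2; channel widths scaled by `width_base` (default 16, i.e.
16/32/64 and 16/32/64/128/1 — sized so the smoke schedule trains in
minutes on one CPU core; `width_base = 32` doubles every width); two
dense layers of 128 units; batch size 32; augmentation by the 8 dihedral
variants (flips and 90° rotations preserve texture).

No deep-learning framework is involved: the package carries a compact,
fully deterministic layer library (im2col convolutions and their exact
adjoints as transposed convolutions, batch normalization, Adam) on base
BLAS matrix products, with every layer verified against finite-difference
gradients in the test suite.

The generator-side objective is the unit-weighted sum of the closed-form
KL divergence, the pixel reconstruction error, the discriminator-feature
similarity and the non-saturating adversarial term, with the
reconstruction terms entering as **per-sample sums** (matching the
per-sample-summed KL). This scaling matters: weighting batch-mean MSEs
instead lets the KL gradient dominate and collapses the posterior (KL →
0, uninformative latents) — observed directly on the synthetic bank.
Each minibatch takes one discriminator update (real vs reconstruction)
and one encoder/generator update. Reported history keeps the
interpretable per-epoch means of all five terms. Downstream clustering
consumes μ only (never samples), so everything after training is
deterministic.

## Pseudo classes and neighborhood profiles

Representations are standardized per column (zero mean, unit variance)
and clustered with seeded k-means (k = 5 by default, 10 restarts);
without standardization, cluster prominence (a 4th-power feature)
dominates the metric. The first two principal components are stored for
inspection. Cluster labels are arbitrary surrogates ("pseudo classes"),
not biological identities.

For every labeled γH2AX+ cell, the spherical neighborhood of radius r
(lateral px) collects the other γH2AX+ cells per class (self excluded;
0 < d ≤ r) and the CD8+ cells. Heatmap entry H[i, j] is the *mean* count
of class-j neighbors over class-i centers — per-center means keep regions
of different density comparable (raw sums available by flag); classes
with no centers are flagged absent, never imputed. CD8-centered counting
(γH2AX+ cells within 32/64/128 px of each CD8+ cell) is reported
separately, in px and µm; both directions of the damage–immune proximity
question are covered. Neighborhood counting is validated against an
O(n²) brute-force oracle (exact integer equality) and is monotone in the
radius by construction.

## Condition comparison

Regions are the exchangeable units. For every heatmap entry and radius,
the difference of condition means (treated − control) is tested by
permuting region condition labels (999 permutations by default, seeded,
two-sided p with the +1 correction). With a single region in a condition,
differences are still reported but p-values are suppressed. This
inferential layer is an extension beyond visual heatmap comparison and is
labeled as such. Its operating characteristics are checked empirically:
type-I rate at α = 0.05 stays near nominal over 100 seeded null
simulations, and a planted doubling of γH2AX+ density near CD8+ cells in
10 regions per condition is detected at p ≤ 0.05.

## The synthetic-data generator

Because the original tissue volumes are not public, validation runs on
synthetic regions with exhaustive ground truth. Nuclei are non-overlapping
axis-aligned ellipsoids (radii ~4–10 voxels, flattened ~0.7× along z),
placed by rejection sampling (an informative error names the achievable
density when a region is overfull). DAPI fills all nuclei; γH2AX renders
only the planted positives; CD8+ cells carry a 1–2 voxel membrane shell
*outside* the nucleus, deliberately forcing the dilation step of the CD8
rule to matter. Additive Gaussian background noise (sd 0.02 by default)
is applied and intensities clamped to [0, 1]; every truth-positive
nucleus has channel mean at least 3 noise-sd above background by
construction. Defaults mirror the targeted acquisition: 302×302×130
voxel regions, ~700 nuclei (the 500–900 range), a 10% positive fraction
and ~20 CD8+ cells; tests use smaller shapes with proportionally fewer
nuclei.

The two default planted texture classes are the field's canonical γH2AX
phenotypes: **focal** (8–16 Gaussian foci of radius 1.5–2.5 voxels over a
0.4 diffuse floor) and **pan-nuclear** (focus-free 0.85 fill). An earlier,
subtler design (6–12 vs 0–2 foci at floors 0.4 vs 0.7) turned out nearly
indistinguishable after per-patch min–max scaling; since the generator's
contract is that planted classes be separable, the phenotypes were widened
to the two canonical patterns. What passing recovery tests show is that
the pipeline separates *separable* texture classes — not that real
repair/apoptosis subtypes are this clean. The generator likewise omits
optical-sectioning blur, shot noise, nucleus shape irregularity and
staining gradients; conclusions about real-tissue performance require
real data.

## Numerical choices and degenerate inputs

* Otsu on a constant channel errors with advice to use a fixed threshold.
* Quantization: level = min(⌊v·n⌋, n−1), monotone, exact at both ends.
* A patch smaller than every configured GLCM offset errors; per-patch
  failures in batch runs are skipped with a log line, not fatal.
* Degenerate (single-voxel-wide) bounding boxes are skipped with a
  warning during patch extraction.
* Non-finite training losses abort with the epoch/batch coordinates (and
  the last checkpoint, when checkpointing is on).
* All randomness (placement, initialization, minibatch order, latent
  noise, k-means restarts, permutations) is derived from explicit seeds;
  two runs with the same seeds are bit-identical on a fixed BLAS.

## Problem sizes used in validation

The shipped validation exercises desk-scale configurations chosen as the
package's own test conditions: smoke training uses 200 patches for 20
epochs at batch 32 without augmentation; class-recovery runs use 50
patches per class over 3 seeds; the permutation calibration uses 100
null simulations of 10 + 10 regions at ~80 cells each; end-to-end
determinism runs a 128×128×32-voxel region with 60 nuclei twice. The
500-epoch reference schedule (`reference_train_config()`) is shipped but
not exercised by the default test run.

## Known limitations

* The texture branches are 2D (central slice); 3D GLCM offsets are an
  extension point, off by default.
* Pseudo classes are not portable across runs without re-matching
  (k-means labels are arbitrary; match by centroid similarity when
  comparing runs).
* The CD8 overlap default (0.15) is geometry-motivated; strongly
  non-convex nuclei or much larger dilation radii warrant re-tuning.
* Heatmaps are pooled per condition (and emitted per region); whether
  pooling or per-region display is preferable is a presentation choice.
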