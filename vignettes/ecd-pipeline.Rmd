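---
title: "Automated endothelial cell density from volumetric corneal imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated endothelial cell density from volumetric corneal imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdquant)
```

## The problem

The corneal endothelium is the innermost single-cell layer of the cornea. It
does not regenerate in vivo, and its pump function keeps the stroma
transparent, so its cell density (ECD, cells/mm²) is the tissue-quality
metric eye banks use when selecting donor corneas for transplantation. The
clinical standard — specular microscopy with a technician manually selecting
50–100 cells in a ~0.1–0.2 mm² field and extrapolating — suffers from
selection bias, sampling error, and inter-operator variability.

Volumetric optical coherence microscopy images the whole cornea in 3-D over a
1 mm² field at micron-scale resolution, through the sealed viewing chamber
and without tissue contact. That raises two image-analysis problems this
package solves:

1. the endothelium is a *curved* thin sheet inside the volume, so no single
   depth slice shows the whole mosaic — it must be digitally flattened;
2. the cells in the flattened en-face view must be segmented and counted
   automatically, without a human selecting "nice" cells.

Because no public volumetric corneal dataset with cell-level ground truth
exists, the package includes a synthetic phantom generator whose outputs
carry exact ground truth; every stage is validated against it.

## Flattening model

The endothelial depth is modelled as a bivariate quadric height function

$$z(x, y) = c_0 + c_1 x + c_2 y + c_3 x^2 + c_4 x y + c_5 y^2,$$

the second-order approximation of a spherical cap, which the central cornea
is locally. A plane cannot represent the curvature; an exact sphere
complicates the linear solve for no accuracy gain over a 1-mm field. The
fitting pipeline is:

1. **Gaussian blur** (`gaussian_blur()`, default σ = 1 voxel, separable,
   kernel truncated at 4σ) for noise reduction;
2. **Huang fuzzy thresholding** (`huang_threshold()`): the threshold
   minimizes the total fuzziness $S(t) = \sum_g h(g)\,H_f(\mu_t(g))$ with
   membership $\mu_t(g) = 1/(1 + |g - m(g,t)|/C)$, where $m(g,t)$ is the mean
   gray level on $g$'s side of $t$, $C$ the gray-level range, and $H_f$ the
   natural-log binary entropy; the smallest minimizer wins ties, and the
   mask is `intensity > t`. Histograms are quantized to 256 levels of the
   intensity range by default;
3. **Majority (median) filtering** (`median_filter()`, radius 1): each voxel
   takes the majority value of its 3³ neighbourhood (odd count — no ties;
   nearest-edge replication at boundaries), suppressing salt-and-pepper
   binarization noise;
4. **Candidate extraction + RANSAC** (`extract_surface_candidates()`,
   `ransac_fit_surface()`): per lateral position the *deepest* foreground
   voxel is a surface candidate, because the endothelium is the
   posterior-most bright layer (an anterior mode exists behind a flag).
   RANSAC repeatedly samples 6 points (the minimal quadric set), counts
   candidates within 2 voxels (≈ 3 µm, matching the observed axial extent of
   endothelial visibility), keeps the consensus-maximal model, and refits on
   its inliers. 500 iterations; deterministic given the seed;
5. **Slab max-intensity projection** (`flatten_to_enface()`): per lateral
   position, the maximum over 1 voxel above to 6 voxels (≈ 9 µm) below the
   fitted surface, absorbing residual fit error and the full axial extent of
   the endothelial signal. The projection reads the *original* volume; the
   blurred copy only drives surface estimation, so cell contrast is not
   degraded.

Two choices here are the package's own resolutions of genuinely open design
points:

* **Surface recentering.** The deepest-voxel rule lands on the posterior
  *boundary* of the binarized layer, which sits 2–4 voxels deep of the
  intensity peak after blurring — so a slab hung 1 voxel above that boundary
  can miss the bright sheet entirely. `flatten_endothelium()` therefore
  shifts the fitted surface by the median per-column offset to the local
  axial intensity maximum (searched ±5 voxels) before projecting. This is a
  single deterministic scalar correction; with it, surface error against
  phantom truth stays below one voxel.
* **Consensus floor at 0.35.** When the Huang threshold lands close to the
  dark posterior-chamber level, a large minority of columns acquire spurious
  deep candidates. The consensus-maximal quadric is still correct in these
  cases, but its inlier share can dip below one half; a 0.5 floor would then
  reject exactly the corrupted-but-recoverable volumes a robust estimator
  exists for. The floor remains configurable.

The historical 1-D alternative — assigning each A-scan the depth of its own
maximum — is included as `flatten_argmax()`. On volumes with folds or noise
it produces line discontinuities; `count_depth_discontinuities()` quantifies
this (4-neighbour pairs whose projection source depths differ by > 2
voxels), and on folded phantoms the 1-D baseline shows roughly an order of
magnitude more discontinuities than the surface fit.

## Segmentation model

Each pixel of the flattened image is labelled **cell border**, **cell
interior**, or **noise** (`classify_pixels()`). Two interchangeable backends
satisfy the same contract:

* `classical_backend()` — deterministic: divide out a heavily smoothed copy
  (σ = 40 px) to cancel vignetting and fold attenuation, smooth lightly
  (σ = 0.5 px), and split at a Huang threshold of the normalized histogram;
  dark ridges between the hyper-reflective interiors become the border
  class. Pixels whose background falls below 25% of its median are noise. A
  contrast-free image yields no border pixels.
* `cnn_backend()` + `train_cnn_backend()` — a patch-centred neural
  classifier (9×9 window in, centre-pixel class out) trained with minibatch
  stochastic gradient descent: momentum 0.9, initial learning rate 10⁻³, L2
  regularization 5·10⁻⁴, minibatch 16, at most 400 epochs. Augmentation is
  restricted to geometry-preserving transforms — translations up to ±10 px
  in both axes (as sampling-centre jitter), specular reflections, and
  right-angle rotations; scaling and skewing are structurally impossible, so
  cell morphology and size statistics are never distorted. Training is
  seeded and reproducible.

Post-processing (`postprocess_to_cells()`) mirrors standard practice: the
border mask is dilated by a radius-2 disc to close small gaps, thinned to a
one-pixel skeleton (Zhang–Suen, with a sequential simple-point cleanup so no
2×2 block survives), and the 4-connected components of the complement become
candidate cells. Regions smaller than 100 px² or larger than 750 px² are
excluded (the bounds themselves are retained — the exclusion rule is
"smaller than" / "larger than"); regions with more than 20% noise-class
pixels are discarded as noisy areas (the 20% is a tool choice, exposed as a
parameter). Survivors are relabelled in raster order. `merge_correct()`
reproduces manual correction of under-segmented cells: user strokes join the
border set and only the touched regions are re-labelled and re-filtered.

## Quantification

`crop_central_disc()` rasterizes a central analysis disc (default 0.5 mm
diameter — the corneal periphery is dimmer because the tissue tilts away
from the optical axis, so analysis is restricted to the centre; at a
typical 3000 cells/mm², the ≈ 0.2 mm² disc holds ≈ 600 cells, 6–12× more
than manual selection assesses). `compute_ecd()` counts retained cells whose
centroid lies inside the disc and divides by the analysis area, so
`ecd × area = n` exactly. The default area is the disc mask's true pixel
count; `area = "nominal"` uses π(d/2)² for the textbook relation (600 cells
in 0.2 mm² ↦ 3000 cells/mm² exactly). Centroid inclusion is deterministic
and unbiased on average for boundary-straddling cells; an
entirely-inside rule is available. The pipeline classifies the *full*
en-face image and applies the disc only at counting, so rim-clipped cells
are never spuriously dropped by the size filter.

## Method agreement

`summarize_agreement()` reports, for a paired ECD table (reference method
first): the mean difference, the Bland–Altman 95% limits of agreement
(1.96 × sample SD of the differences, n−1 denominator, no CI on the limits),
the squared Pearson correlation (flagged undefined under zero column
variance), and the mean *signed* percent difference with the reference
method as denominator — the convention that reproduces the per-cornea
percent-difference column of the bundled ten-cornea example table exactly.

```{r agreement}
pairs <- ecd_method_pairs()
summarize_agreement(pairs[c("cornea", "sm_ecd", "gdocm_ecd")])
```

Note the correlation: these ten pairs give R² = 0.83, i.e. a Pearson
correlation coefficient r = 0.91.

## The phantom generator

`generate_mosaic()` builds the cell pattern: seed points drawn uniformly on
the field, a Lloyd (centroidal-Voronoi) relaxation applied `relax` times
(default 2), exact nearest-seed assignment for every pixel, and a border
band (default 2 px) along Voronoi edges. Healthy endothelium is a
near-regular hexagonal mosaic with a cell-area coefficient of variation
around 0.3–0.4; two relaxation steps reproduce that (CV ≈ 0.4), and then
the [100, 750] px² size filter covers ≈ 99% of ground-truth cells at
3000 cells/mm² — consistent with the filter's design premise of ≥ 95%
coverage. Unrelaxed uniform seeds (`relax = 0`) give a Poisson-Voronoi
mosaic with far heavier area tails (CV ≈ 0.5–0.6, ~90% coverage), which
real endothelium does not show; it remains available for stress testing.

`generate_volume()` paints the mosaic as a bright 3-voxel shell (peaked at
the stored integer surface height, so the noiseless per-column argmax equals
the stored truth) on a quadric surface, above a dark posterior chamber and
below dimmer stroma, then applies quadratic radial vignetting, optional
straight multiplicative fold bands, and additive Gaussian noise clamped at
zero. Relative intensities default to interior 1.0, border 0.45, stroma
0.25, posterior 0.05; noise SD 0.1 (shell SNR 10, border-step SNR ≈ 5.5);
vignette 0.3. No quantitative noise or contrast characterization of real
volumetric endothelial images is published, so these are realistic free
parameters, swept in tests rather than calibrated. Everything is a pure
function of (parameters, seed).

What the phantoms do *not* emulate: coherent speckle statistics, the defocus
point-spread function, keratocytes and other stromal texture, epithelial
layers, and real fold geometry (bands are straight and sharp-edged).
Passing phantom tests therefore demonstrates correctness of the geometry,
segmentation and counting machinery under controlled degradation — not
clinical performance on real corneas.

## Numerical choices and degenerate inputs

* Huang threshold: smallest minimizer wins ties; single-level histograms are
  rejected (no threshold separates one mode).
* RANSAC: rank-deficient minimal samples are skipped; fewer than 6 candidate
  points is a precondition violation, low consensus a distinct fit-failure
  condition.
* Majority filter: odd neighbourhood — no ties by construction.
* Skeleton: Zhang–Suen staircase remnants are removed by sequential deletion
  of simple points only (single 8-connected foreground component in the
  neighbour ring, at least one free 4-neighbour), preserving skeleton
  connectivity and complement 4-topology.
* Labels: components are numbered in raster order of their first pixel, so
  runs are bit-reproducible; all stochastic steps take explicit seeds, and
  `run_pipeline()` derives stage seeds from one top-level seed.
* Empty cases: an empty border mask leaves the frame as one candidate region
  (dropped by the size filter whenever it exceeds `max_area`); zero counted
  cells give ECD 0 with morphometry flagged undefined.

## Problem sizes used in validation

The bundled tests and the acceptance script validate on phantoms of
560×560×44 voxels (0.31 mm² field) for end-to-end density recovery at
2000–3500 cells/mm², 240×240×36 for fold-artifact comparisons, and
1000×1000 mosaics for density consistency — sizes chosen so the full
validation suite runs in minutes on a single core while keeping the 0.5-mm
analysis disc (500 px at 1 µm/px) inside the field. The same code paths
scale unchanged to full 1000×1000×100 acquisitions.

## Known limitations

* The quadric surface cannot follow high-frequency deformation (deep folds);
  fold regions are handled by outlier rejection and the projection slab, not
  by modelling the fold.
* The classical backend assumes dark-border / bright-interior polarity.
* The patch-net backend ships untrained; it is trained per dataset (on
  phantoms in the tests). No pretrained weights are distributed, and the
  published Dice scores of the original CNN are not reproducible here
  because the underlying annotated images are not public.
* True ECD of a phantom counts *all* cells with centroids in the disc,
  while the pipeline excludes size-filter outliers, so a small systematic
  undercount (≈ 1%) remains even in noiseless conditions.
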