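# ecdquant

Automated, unbiased endothelial cell density (ECD) analysis of donor corneas
imaged in 3-D with volumetric optical coherence microscopy.

The corneal endothelium — the non-regenerating pump layer that keeps the
stroma transparent — is graded by eye banks through its cell density
(cells/mm²). The clinical standard, specular microscopy with manual
selection of 50–100 cells, suffers from selection bias and sampling error.
`ecdquant` implements the alternative: image the cornea volumetrically over
a 1 mm² field, digitally flatten the curved endothelial sheet, segment every
cell in a central analysis disc, and count them all.

## What it computes

Given a volume *V(x, y, z)*, the package:

1. **Flattens** the endothelium: Gaussian blur → Huang fuzzy threshold
   (minimizing S(t) = Σ h(g)·H<sub>f</sub>(μ<sub>t</sub>(g)) with
   μ<sub>t</sub>(g) = 1/(1 + |g − m(g,t)|/C)) → 3-D majority filter →
   RANSAC fit of a quadric height surface
   z(x,y) = c₀ + c₁x + c₂y + c₃x² + c₄xy + c₅y² to the deepest bright voxel
   per A-scan → max-intensity projection of a thin slab about the surface.
2. **Segments** the flattened image into cell border / cell interior / noise
   (deterministic classical backend, or a trainable patch-net backend with
   the standard SGD recipe: momentum 0.9, LR 1e-3, L2 5e-4, batch 16), then
   dilates the border mask, skeletonizes it, takes 4-connected complement
   components as cells, and excludes regions outside [100, 750] px².
3. **Counts**: ECD = n / A on a central 0.5-mm analysis disc (centroid
   inclusion; ecd·area = n exactly), plus per-cell morphometry.
4. **Compares methods**: mean difference, Bland–Altman 95% limits of
   agreement (1.96·SD of differences), Pearson R², signed percent
   difference against the reference method.

A synthetic phantom generator (Voronoi cell mosaics painted as a curved
bright shell with noise, vignetting, and fold bands, plus exact ground
truth) makes every stage testable without clinical data.

## Worked example

```r
library(ecdquant)

# a 0.31-mm^2 phantom at ~3000 cells/mm^2 with noise, vignetting, curvature
m  <- generate_mosaic(n_cells = 941, height = 560, width = 560, rng_seed = 3)
ph <- generate_volume(m, dome_surface(c(560, 560), apex_depth = 20, sag = 15),
                      depth = 44, noise_sd = 0.1, vignette_strength = 0.3,
                      rng_seed = 4)
m$true_ecd
#> [1] 3081.013

res <- run_pipeline(run_config(seed = 5), ph)
res$report
#> <ecd_report> 600 cells / 0.1964 mm^2 = 3056 cells/mm^2 (mean area 289 um^2, CV 0.33)
res$surface
#> <surface_model> z(x,y) quadric, 180070/313600 inliers (thr 2 voxels), RMSE 0.575
```

The pipeline recovers the phantom's true density within ~1%: 3056 vs 3081
cells/mm² (the small deficit is cells excluded by the size filter). The
`ecd_report` fields satisfy `ecd × analysis_area = n_cells` exactly.

Paired-method agreement on the bundled ten-cornea example table
(specular microscopy vs automated volumetric counting):

```r
summarize_agreement(ecd_method_pairs()[c("cornea", "sm_ecd", "gdocm_ecd")])
#> <agreement_report> n = 10
#>   mean difference (B - A): 99.6
#>   95% limits of agreement: +/- 268.3
#>   Pearson R^2: 0.83
#>   mean percent difference: 3.7%
```

A thin CLI ships in `inst/cli/ecdquant` with subcommands `simulate`,
`flatten`, `segment`, `count`, `compare`, and `run`.

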