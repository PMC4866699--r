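# infodim

Information fractal dimension (D1) of binary brain-structure masks, with
validation phantoms and the nonparametric group-comparison pipeline used in
subcortical morphometry.

## What it is for

Conventional volumetry reduces a segmented brain structure to one number that
scales with head size and says nothing about surface shape. Fractal
complexity analysis asks a different question: how does the structure's
detail change with the scale at which you measure it? For a binary mask — a
subcortical gray-matter structure (hippocampus, thalamus, caudate, putamen,
pallidum, amygdala, nucleus accumbens, brainstem) segmented in standard
space at 1.5 mm voxels — the package covers the set with grids of cubes of
side *r* = 2…30 voxels, computes the Shannon entropy of the box-occupancy
probabilities

> p<sub>i</sub> = N<sub>i</sub>(r) / N<sub>all</sub>,  I(r) = −Σ p<sub>i</sub> log p<sub>i</sub>

and estimates the **information dimension** D1 as the slope of I(r) versus
log(1/r) over the linear scaling regime, selected by an iterative breakpoint
fit that trims the oscillatory large-box points. D1 is a scale-free shape
descriptor, dissociated from volume: for solid 3D structures it typically
lies between 2 and 3, with lower values indicating a less complex surface.
It is the kind of measure used to compare, e.g., schizophrenia patients with
matched controls, where reduced hippocampal D1 has been reported.

The package is intended for neuroimaging researchers who already have
segmentation masks (e.g. FSL FIRST outputs) and want per-structure D1 values
plus the downstream case-control statistics.

## Worked example

```r
library(infodim)

## dimension of one structure (here: a 60 mm solid-sphere phantom)
fit <- fd_d1(phantom_sphere(60, 1.5))   # or fd_d1("mask.nii.gz", threshold = 0)
print(fit)
#> structure: sphere_d60mm
#> information dimension D1 = 2.7032  (R^2 = 0.9990)
#> retained box range: 2-20 cells (19 points)
#> structure size: 33552 voxels, 113238.00 mm^3
```

D1 ≈ 2.70 for a voxelized solid ball of radius 20 cells (an ideal solid has
dimension 3; boundary boxes depress the finite-size estimate), fitted over
the full informative box range with R² = 0.999, from 33,552 occupied voxels
(113.2 cm³). `plot(fit)` draws the I(r) versus log(1/r) diagnostic with the
retained points and fitted line.

```r
## phantom battery: estimates against known dimensions
fd_validate(cantor_seeds = 1:10)
#>                           phantom theoretical computed min_r max_r
#>                            circle    1.000000 1.052218     2     7
#>                           koch_n4    1.261860 1.290734     2    21
#>  cantor3d_p0.7 (mean of 10 seeds)    2.485427 2.340560     2    30

## two-group comparison on a synthetic cohort (19 vs 19, true effect 0.025)
co <- simulate_cohort(19, effect = 0.025, noise_sd = 0.015, seed = 7,
                      structures = c("Left.Hippocampus", "Left.Thalamus"))
fd_group_summary(co, n_boot = 2000, seed = 1)
#>         structure median_HC min_HC max_HC median_SCZ min_SCZ max_SCZ   u     p
#>  Left.Hippocampus    2.1748 2.1454 2.1889     2.1465  2.1215  2.1706 328 0e+00
#>     Left.Thalamus    2.1740 2.1481 2.1870     2.1553  2.1217  2.1685 314 1e-04
#>  shapiro_p_HC shapiro_p_SCZ u3  u3_lo u3_hi fdr_significant
#>        0.1486        0.9813  1 0.7895     1            TRUE
#>        0.1843        0.0687  1 0.7895     1            TRUE
#>
#> BH FDR at alpha = 0.05: realized critical p 9.719132e-05
```

Per structure: group medians and ranges, the two-tailed Mann-Whitney U and
p, Shapiro-Wilk screens, Cohen's U3 with a seeded bootstrap CI, and the
Benjamini-Hochberg FDR flag across all structures. `fit_interaction()` adds
the post-hoc `fd ~ group * age` (or `* sex`) models with per-group simple
slopes, and `spearman_rho()` the D1-volume association.

A command-line front end is installed as `exec/fdtool` with subcommands
`phantom`, `compute` (batch masks → CSV + run manifest), `stats` and
`validate`.

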