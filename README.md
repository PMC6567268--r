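# microangio

Quantitative fingerprinting of 3D microvascular angioarchitectures from
binary confocal z-stacks.

`microangio` is for researchers who image immunostained microvasculature
(e.g. CD31⁺ signal in brain cortex) and want to quantify how a vascular
*network* — not individual vessels — changes between conditions: rarefaction,
loss of small capillaries, altered intervascular distances. It implements a
mathematical-morphology pipeline that reduces each z-stack to a seven-
parameter, near-linear "fingerprint", and compares fingerprints between
groups with the field's conventional statistics.

## The method

For a binary isotropic stack the pipeline computes:

1. **Lumen recovery** — size-capped 3D close-and-fill (26-neighborhood
   closing, then filling of enclosed 6-connected cavities smaller than
   1200 voxels), so hollow immunostained walls become solid vessels.
2. **Caliber classification** — every foreground voxel is scored by the
   minimal cross-section *a*: the area of the 8-connected in-plane
   component through the voxel, minimized over the three Euclidean planes.
   Classes are delimited by a geometric ladder
   `T_k = round(offset · ratio^k)` voxels; with the defaults
   (offset 4 voxels ≙ 1.64 µm², ratio 1.8, six classes) the boundaries are
   1.6 / 2.9 / 5.3 / 9.4 / 17 / 31 / 56 µm², i.e. circle-equivalent
   diameters ≈ 1.4–8.4 µm. Sub-offset voxels form a normalizing-only
   seventh class; anything above 56 µm² is excluded.
3. **Progressive trees** — cumulative unions of classes from the largest
   caliber down (k = 1…6), intersected with the originally acquired
   signal, each quantified as percent volume occupancy (Vol%).
4. **Dispersion (nHv 95%)** — each tree is dilated with the repeating
   6/18/26-neighborhood ("rhombicuboctahedral") element cycle until it
   fills 95% of the volume; the fractional step count, minus the steps
   needed to match the signal amount of the densest compared sample, is
   the normalized dispersion index nHv 95%.
5. **Fingerprint** — OLS regression of nHv95 on Vol% across the six trees.
   Its parameters: left end (a, b), slope c, X-projection d, right end
   (e, f), Y-projection g. Steeper slopes and shorter X-projections signal
   a rarefied network with increased intervascular distances.
6. **Group statistics** — slopes by ANCOVA F-test on pooled points
   (F with (1, n−4) df), amount parameters a/d/e by unpaired t-tests,
   dispersion parameters b/f/g by Mann–Whitney with Gaussian
   approximation.

A synthetic vascular-tree generator (`synth_config()`,
`generate_network()`, `make_cohort()`) produces ground-truth branching
networks spanning the full caliber range, with a rarefaction parameter
that deletes thin branches — so the entire pipeline is testable without
animal data.

## Worked example

Two synthetic groups, 4 animals × 3 stacks each at a 96³-voxel grid:
a control condition and a rarefied condition in which half of the thin
vessel branches (the three smallest caliber classes) are deleted.

```r
library(microangio)

caliber_ladder(4, 1.8, 6, 0.41)
#> caliber_ladder: offset 4 voxels, ratio 1.8, 6 classes (voxel area 0.41 um^2)
#>   thresholds [voxels]: 4, 7, 13, 23, 42, 76, 136
#>   thresholds [um^2]:   1.64, 2.87, 5.33, 9.43, 17.22, 31.16, 55.76
#>   equivalent diameters: 1.4 to 8.4 um

base <- synth_config(grid_shape = c(96L, 96L, 96L), n_roots = 2L,
                     max_segments = 1500L)
rare <- synth_config(grid_shape = c(96L, 96L, 96L), n_roots = 2L,
                     max_segments = 1500L, rarefaction = 0.5)
coh <- make_cohort(base, rare, n_units = 4, stacks_per_unit = 3,
                   master_seed = 7, group_names = c("wt", "twi"))
res <- run_pipeline(run_config(stacks = coh$stacks, grouping = coh$manifest))
res
#> angio_result: 24 stacks, 8 units, group(s): wt, twi
#>   normalizing Vol%: 5.297
#>   per-unit fingerprints:
#>  unit_id group  slope     r2      a     b     d     e     f      g
#>    wt_u1    wt -2.662 0.5124 1.1610 23.82 3.064 4.225 15.66  8.156
#>    wt_u2    wt -5.065 0.8240 1.2460 31.65 3.099 4.345 15.95 15.700
#>    wt_u3    wt -4.470 0.7610 1.2590 28.94 3.207 4.466 14.60 14.340
#>    wt_u4    wt -5.720 0.9151 1.0260 33.00 3.138 4.164 15.05 17.950
#>   twi_u1   twi -7.116 0.8102 1.1630 35.35 1.876 3.040 22.00 13.350
#>   twi_u2   twi -6.041 0.7971 1.0760 35.91 2.060 3.136 23.47 12.450
#>   twi_u3   twi -7.491 0.5819 0.8942 38.69 2.092 2.987 23.02 15.670
#>   twi_u4   twi -9.019 0.6990 1.0540 38.91 1.889 2.943 21.87 17.040
#> slope F-test: F(1, 140) = 21.8, p = 7.019e-06
#>   slope A = -4.4707, slope B = -7.6602
#> parameter comparison (flagged at p < 0.05):
#>  parameter         test statistic         p degenerate    mean_A    mean_B significant
#>          a            t    1.6280 1.546e-01      FALSE  1.172883  1.046725       FALSE
#>          b mann-whitney   -2.1650 3.038e-02      FALSE 29.352097 37.217772        TRUE
#>          d            t   17.9100 1.950e-06      FALSE  3.127298  1.979545        TRUE
#>          e            t   16.1800 3.543e-06      FALSE  4.300181  3.026270        TRUE
#>          f mann-whitney   -2.1650 3.038e-02      FALSE 15.316944 22.589686        TRUE
#>          g mann-whitney    0.1443 8.852e-01      FALSE 14.035154 14.628086       FALSE
```

Reading the output: the rarefied group's fingerprint slope is
significantly steeper (−7.7 vs −4.5, F-test p ≈ 7·10⁻⁶), its X-projection
d is shorter (less volume contributed by sub-maximal calibers) and its
right-end X position e is left-shifted (total analyzed signal reduced),
while the left-end amount a and the Y-projection g do not differ — the
signature of small-vessel rarefaction with unchanged large-vessel content.

Greyscale multi-page TIFFs can be analyzed the same way via
`run_config(paths = ..., spacing = c(z, xy, xy))`, which resamples to
isotropic voxels and auto-thresholds before the morphology; a thin
command-line front end with `synth` and `run` subcommands is installed at
`inst/scripts/microangio.R`.

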