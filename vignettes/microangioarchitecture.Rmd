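---
title: "Fingerprinting 3D microangioarchitectures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting 3D microangioarchitectures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the model behind `microangio`, the choices made where
the design was genuinely open, and what the synthetic validation does and
does not establish. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The analysis in one paragraph

A binary, isotropic 3D image of an immunostained microvascular network is
decomposed into **caliber classes**: every foreground voxel is scored by the
area of the smallest 2D vessel cross-section through it (8-connected
in-plane component, minimized over the three axis-aligned planes), and
binned against a geometric ladder of area thresholds. Classes are then
cumulated from the largest caliber downward into **progressively
reconstituted vascular trees**. Each tree is reduced to two numbers: its
percent volume occupancy (Vol%) and its spatial dispersion, the **nHv 95%
index** — the fractional number of structured dilation steps needed to
expand the signal to 95% of the volume, normalized for signal amount.
Plotting nHv 95% against Vol% across the six analyzed trees gives a
near-linear **fingerprint**; its ordinary-least-squares line carries seven
interdependent parameters (left end a/b, slope, X-projection d, right end
e/f, Y-projection g) that are compared between experimental groups.

## Caliber ladder

Thresholds grow geometrically from an offset: `T_k = round(offset * ratio^k)`
in **voxels**, `k = 0..6`, then convert to µm² through the voxel area.
The quantization to integer voxel counts is part of the definition —
cross-sections are integer voxel counts — and it is what reproduces the
conventional printed class boundaries (e.g. `round(4 * 1.8^3) = 23` voxels
= 9.4 µm², where unrounded multiplication would give 9.6 µm²). With the
defaults (offset 4 voxels at 0.64 µm spacing, ratio 1.8, six classes) the
analyzed calibers span circle-equivalent diameters of about 1.4–8.4 µm.
Class intervals are half-open and upper-inclusive (`T_low < a <= T_high`),
making printed ranges such as "56 to 31 µm²" non-overlapping. Voxels at or
below the offset form a seventh, sub-offset class used **only** to complete
the normalizing total; voxels above the top threshold are flagged
over-range and excluded everywhere, because the analysis is restricted to
microvessels below ~56 µm² cross-section.

## Preprocessing

* **Isotropy.** Confocal stacks are anisotropic (coarser in z). Only the
  z-axis is resampled, by linear interpolation, to the in-plane spacing;
  the kernel the original toolchain used is unpublished, so linear was
  chosen as the smooth, order-preserving standard. Binarization runs after
  the isotropic conversion.
* **Binarization.** Iterative-intermeans (IsoData-variant) threshold on the
  whole-stack histogram; foreground is strictly above the threshold.
  Integer data are binned at unit width (up to 16-bit); other data use 256
  equal-width bins. Constant stacks are a hard error, not a silent guess.
* **Lumen recovery.** Immunostained walls image as hollow tubes. A
  26-neighborhood closing (default 2 cycles) is followed by cavity filling:
  every 6-connected background component of the closed map that does not
  touch a stack face and is smaller than `max_fill_voxels` (default 1200)
  is filled. The cap is applied to candidate fill components once, after
  the closing — the interpretation that satisfies the intent of not
  swallowing intervascular space. Complementary connectivities (26 for
  foreground, 6 for background) avoid topological paradoxes, and the output
  is always unioned with the input, so no acquired voxel is ever lost.
  Classification runs on the filled map; afterwards the class map is
  intersected with the original binary signal so that only acquired signal
  is analyzed (filled lumina drop out, walls keep their class).

## Dispersion by structured dilation

The dispersion index iterates binary dilation and records occupancy.
The element sequence is part of the index definition:

* The `"rhombicuboctahedral"` scheme cycles the 6-, 18- and 26-neighborhood
  elements; the Minkowski sum of one full cycle is a rhombicuboctahedron-like
  solid, a much better approximation to Euclidean expansion than any single
  cubic element. The original plugin's exact sequence is unpublished, so the
  scheme is a named, pluggable strategy, and every compared sample must use
  the same one. Absolute index values are scheme-dependent; comparative
  quantities (slopes, differences) are scheme-stable.
* Step counts are fractional: if a target occupancy falls between steps
  k−1 and k, the count interpolates linearly within the final step.
* Dilation is clipped at the stack faces — the acquired field is the
  reference volume. Targets default to 90/95/99%; the 95% index is the
  analysis quantity.
* **Normalization.** Raw counts confound dispersion with amount. The
  normalizing image is the total architecture of the sample with the
  maximal Vol% among all samples compared jointly (per-group normalization
  exists behind `norm_scope = "group"` but is off by default). For each
  architecture, the fractional steps needed to dilate it from its own Vol%
  up to the normalizing Vol% (same interpolation rule, on its own trace)
  are subtracted: `nHv_p = Hv_p − offset`. The normalizing sample itself
  always gets offset 0.

The trace implementation tracks the active front (foreground voxels with a
background 26-neighbor) instead of rescanning the grid; a test asserts
exact agreement with step-by-step full-grid dilation.

## Fingerprint and statistics

Within a unit (animal), points from all of its stacks are pooled; the
fingerprint line is the OLS fit of nHv95 on Vol% over the six analyzed
architectures (the sub-offset-inclusive total is a normalization device,
not a plotted point; `include_suboffset_point = TRUE` restores the 7-point
variant). Endpoint X positions (a, e) are the mean Vol% of the first and
last architectures; endpoint Y values (b, f) are read off the fitted line
at those positions (a raw-point option exists). `d = e − a`, `g = b − f`.

Group comparisons follow the convention of the field:

* **Slopes**: ANCOVA-style F-test on the pooled per-group point clouds —
  full model with separate slopes vs reduced model with a common slope,
  `F = (RSS_r − RSS_f) / (RSS_f / (n − 4))` on (1, n − 4) df.
* **Amount parameters** a, d, e: two-sided unpaired t-tests (pooled
  variance); a zero-variance difference is flagged as degenerate rather
  than reported as an infinite statistic.
* **Dispersion parameters** b, f, g: two-sided Mann–Whitney with Gaussian
  approximation. Continuity correction is on by default; tie correction is
  off by default (ties have probability zero for continuous indices); both
  are toggleable. Per-unit slopes are reported descriptively but not
  re-tested here — the slope inference is the F-test.

No multiple-testing correction is applied, matching the source convention;
differences are flagged at p < 0.05.

## The synthetic generator

`synth_config()`/`generate_network()` grow random branching trees: segments
of mean length 18 µm with bounded turning (≤30°), bifurcation with
probability 0.65 per segment, radius multiplied by 0.75 at each bifurcation
from 3.2 µm roots down to a 0.7 µm floor, growth reflected at the field
boundary so networks stay space-filling, and capsules rasterized by voxel
centers. The defaults were fixed on realism grounds before any acceptance
measurement: all six caliber classes populated, total Vol% around 3–4%,
several hundred segments per 192×192×96-voxel stack at 0.64 µm — the
desk-scale analogue of a 327×327 µm confocal field.

**Rarefaction** emulates thin-capillary loss: a fraction of the maximal
thin subtrees (all segments at or below `rarefy_radius_um = 1.75` µm,
i.e. the three smallest analyzed classes) is deleted whole, branch plus
descendants. Deleting whole branches rather than single terminal segments
is the physiologically meaningful reading of capillary regression, and it
is what actually halves the small-class signal at `rarefaction = 0.5`
(measured class-histogram ratios ~0.45–0.55 for classes 4–6, ~0.85–0.95
for classes 1–3).

What the generator does **not** emulate: anastomoses and loops, hemodynamic
consistency, intussusception, staining noise, or anisotropic blur. Passing
tests on synthetic cohorts therefore validate the *pipeline arithmetic and
its comparative behavior under a known caliber spectrum*, not the biology
of any particular tissue.

## Problem sizes used by tests and the acceptance script

Chosen as the package's own desk-scale defaults: linearity checks run 5–10
stacks at the default 192×192×96 geometry; the two-group contrast runs
4 units × 3 stacks per group at 96³; Monte-Carlo calibration runs 200
replicate cohorts at 28×56×56 (unit-spacing variant with radii rescaled so
all classes populate). Seeds are fixed or derived arithmetically from a
single master seed, so every number is exactly reproducible.

## Known limitations

* **Pseudo-replication in the pooled slope F-test.** The F-test treats the
  six points of every stack as independent observations, but they are
  strongly clustered — each stack is nearly its own line. Under replicate
  resampling of identical-config cohorts, the test's empirical size is well
  above the nominal 0.05 (~0.35 at the calibration design used in the
  acceptance suite), and the inflation *grows* with stack quality, because
  within-stack scatter shrinks faster than between-stack slope
  heterogeneity. The package reproduces the conventional test faithfully —
  and its points-level size is correct when points are genuinely
  independent (tested) — but group-level slope p-values should be read as
  descriptive unless units, not points, are the replication level. A
  conservative alternative is comparing the per-unit slopes reported in
  `unit_params`.
* Absolute nHv values depend on the dilation scheme; only comparisons
  under a shared scheme are meaningful.
* The isotropic interpolation kernel may differ marginally from the
  original toolchain's unpublished choice.
* Junction voxels of overlapping thick segments can exceed the top
  threshold and are excluded as over-range, exactly as in the analyzed
  caliber window of real data.
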