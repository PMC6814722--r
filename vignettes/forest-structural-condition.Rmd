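---
title: "Scoring forest structural condition and integrity, and validating it with lidar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring forest structural condition and integrity, and validating it with lidar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestintegrity)
```

## The indices

Humid-tropical forest maps have historically tracked *extent*; this
package implements two indices that track *quality* of stand structure,
plus the lidar-based procedure used to check that they mean what they
claim.

**SCI — Forest Structural Condition Index.** Each 30 m cell is scored
1–18 by crossing three classifications:

* canopy cover (%): `<25`, `25–75`, `>75–95`, `>95`;
* canopy height (m): `0–5`, `>5–15`, `>15–20`, `>20`;
* loss epoch from the loss-year code (0 = no stand-replacing loss since
  2000, k = loss in year 2000+k): recent (2013–2017), mid (2001–2012),
  none.

Any recently disturbed, short (≤5 m) or open (<25 % cover) cell scores 1.
Otherwise the mid-epoch block runs 2–10 and the no-loss block 10–18,
increasing with height class then cover class, so 18 is a tall,
closed-canopy stand undisturbed since 2000. Boundary conventions are
taken from the published executable form of the classification rather
than the table headers alone: cover 25 is forested (the mask uses a
strict `< 25`), height 5 belongs to the shortest class (`<= 5`), and the
upper bound of every interior class is inclusive. Cover exactly 75 falls
in the 25–75 class, forced by the `>75–95` label on the next class; the
source never states this case in executable form, so it is a documented
convention here.

**FSII — Forest Structural Integrity Index.** SCI is discounted by
human pressure: the Human Footprint score (HFP, 0–50) maps to Low
(weight 1, HFP < 4), Medium (5, 4 ≤ HFP ≤ 15) or High (10, HFP > 15),
and

$$\mathrm{FSII} = \mathrm{SCI} \times \frac{1}{\text{pressure weight}},$$

giving values 0.1–18. The printed reference table's Low-pressure entry
for SCI 1 reads 0.2 where the formula gives 1.0; `fsii_value()` follows
the formula and the discrepancy is treated as a printing erratum, not
silently reproduced. Because HFP is distributed at ~1 km while SCI is at
30 m, `compute_fsii()` by default upsamples HFP to the 30 m grid by
nearest neighbour; `at_hfp_resolution = TRUE` instead aggregates SCI to
the coarse grid by modal value, for the coarse-resolution reading of the
index.

## The validation pipeline

The check that SCI tracks vertical structure uses foliage height
diversity (FHD) from discrete-return airborne lidar:

1. **Ground normalization.** Every vegetation return is converted to
   height above ground using its k = 6 nearest ground-classified returns
   in the x–y plane, weighted by inverse squared distance. An exact hit
   on a ground point short-circuits to that point's elevation; clouds
   with fewer than k ground points use all of them. Ties in distance
   break by input order so results are reproducible. The search is exact
   (grid-bucketed, written in C++) because transect clouds run to
   millions of points.
2. **Filtering.** Heights above 70 m are removed as cloud/sensor noise.
   Slightly negative heights — returns below the interpolated ground —
   are clamped to 0 rather than dropped, so ground-hugging returns still
   count toward point density; the source procedure is silent here and
   dropping them would bias the density rule.
3. **FHD.** Per 30 m cell, heights are binned at 1 m intervals
   (`[i, i+1)`, a point at exactly 70 closing the last bin) and
   FHD = −Σ pᵢ ln pᵢ over occupied bins. The Shannon logarithm is
   natural, the convention of the foliage-height-diversity literature;
   the base is an argument. Cells with vegetation-point density below
   10 pts/m² are masked invalid. The density rule is applied to
   vegetation points only, since density is computed after normalization,
   which is defined for vegetation returns.
4. **Alignment and sampling.** The FHD grid is aligned to the SCI grid
   by bilinear interpolation; SCI cells whose loss code postdates the
   lidar acquisition year are masked (strictly: loss in the acquisition
   year is kept). To be robust to residual misalignment, samples are
   restricted to *cores* of homogeneous SCI patches: rook-connected
   components of constant SCI, at least 3 × 3 cells, with every cell
   within 90 m of the patch perimeter removed. The 90 m rim is measured
   in the Chebyshev metric (erosion by a square element, 3 cells on a
   30 m grid), so diagonal proximity to the perimeter also disqualifies
   a cell; the raster edge counts as perimeter. Applied literally, both
   rules together erode a 3 × 3 patch to nothing — small patches simply
   contribute no samples.
5. **Models.** On the sample table, three nested specifications are
   fitted and ranked by AIC: OLS (`FHD = SCI + e`), a transect random
   intercept, and patch nested in transect. SCI enters as a continuous
   covariate. Mixed models are estimated by maximum likelihood, not
   REML, so AICs are comparable across fits that share fixed effects.
   For mixed models both marginal R² (fixed-effects variance over total)
   and conditional R² (fixed plus random over total) are reported, in
   the variance-partition sense; the conditional value is the headline
   comparator. Patch connectivity (4 vs 8) and the categorical-SCI
   option are switches rather than defaults.

## What the synthetic generator emulates

Real inputs to this kind of validation — multi-transect airborne lidar
archives and the global condition rasters — are not redistributable at
desk scale, so the package carries a first-class generator with two
halves.

`generate_landscape()` grows `n_patches` irregular patches by seeded
stochastic dilation, assigns each a class, then draws every cell's
cover, height and loss code uniformly from that class's admissible
region of the weight table. By construction `compute_sci()` inverts the
generator exactly, which is the end-to-end correctness check for the
raster side. The HFP surface is uniform 0–50 on a 990 m grid (33 cells,
mirroring the ~1 km footprint product on a 30 m grid).

`generate_point_cloud()` lays a Poisson number of vegetation returns per
cell at the class's expected density with heights from a three-stratum
Gaussian mixture (ground-hugging returns, understory, canopy), riding on
a smooth sinusoidal terrain; ground returns sample the terrain exactly.
Defaults: 12 pts/m² vegetation density for every class — comfortably
above the 10 pts/m² validity rule and typical of modern discrete-return
acquisitions — and 1 pt/m² ground density. Canopy top height rises from
4 m (class 1) by 1.8 m per class, and the ground-return share falls with
class, so the closed-form binned entropy of the mixture
(`expected_fhd()`, the oracle for recovery tests) increases strictly
with class. With `saturate = TRUE` (default) classes 15–18 reuse the
class-14 profile, reproducing qualitatively the observed saturation of
FHD above class 14; the switch exists because the saturation is an
empirical finding, not a law.

What the generator does *not* emulate: sensor artefacts (no noise
returns above the canopy, no misclassified ground), occlusion of the
understory under dense canopy, spatially correlated height variation
within a class, non-Gaussian vertical profiles, and real terrain
roughness. Passing tests therefore demonstrate the *pipeline's*
correctness and the statistical machinery's behaviour under known
structure — not that the index achieves any particular R² on real
transects, which depends on the archive itself.

For the mixed-model checks, `simulate_validation_samples()` generates
the sample table directly: FHD linear in SCI (intercept 0.5, slope 0.12
per class, spanning the realistic FHD range ≈0.6–2.7) plus Gaussian
random intercepts at transect (sd 0.3) and patch (sd 0.15) levels and
residual sd 0.1. Under that design — 10 transects × 20 patches × 9
cells, 50 replicates — the nested model beats the transect-only model
beats OLS on AIC in ≥95 % of replicates, the SCI slope is positive in
all of them, and conditional R² never falls below marginal R². These
sizes keep the whole suite to a few minutes on one CPU while leaving the
orderings far from marginal.

## Numerical and design choices

* **Rasters.** North-up grids with square cells in a projected
  (metre-unit) CRS only; cell `(r, c)` owns the half-open box with its
  north-west corner closed, making point-in-cell assignment
  unambiguous. Missing data are `NA` in memory; files carry a sentinel
  (−9999 continuous, 255 byte-coded). GeoTIFF I/O is a deliberately
  minimal single-band, uncompressed reader/writer (pixel scale,
  tiepoint, GeoKey CRS code, nodata tag); files in geographic
  (degree-unit) CRSs are rejected with an instruction to project first,
  because the 30 m cells and 90 m buffers assume metres.
* **Bilinear alignment** interpolates between the four surrounding
  source cell centers; any support touching `NA` yields `NA`
  (conservative contagion), and output cannot overshoot the source
  range.
* **Degenerate fits.** OLS requires ≥3 records and ≥2 distinct SCI
  values; mixed fits require ≥2 groups and raise an explicit error with
  optimizer diagnostics on non-convergence. With no group structure the
  random-intercept fit collapses to OLS (slope difference below 1e−6 in
  tests), which is the expected boundary behaviour, not an error.
* **Determinism.** Every generator takes a seed and identical seeds give
  bit-identical output; kNN ties and patch label numbering are
  order-stable; AIC ties keep input order in `compare_models()`.
* **Problem sizes.** Tests exercise the full pipeline on a 24 × 24-cell
  landscape (~6.7 M points) and the model suite on 50 replicates of
  1 800 samples; these sizes were chosen so each property is measured
  with comfortable margins while the suite stays desk-scale.

## Limitations

The package classifies and validates; it does not produce the global
input layers (tree cover, canopy height, loss year, human footprint)
from satellite data, handle forest *gain*, reproject between CRSs, read
binary LAS/LAZ (use the delimited-text form or convert upstream), or
attempt the published archive's actual AIC/R² values, which are
functions of proprietary-access data. The per-class vertical profiles
are stylised; anyone using the generator to argue about real forests
should treat it as a null model with known structure, nothing more.
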