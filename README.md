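# forestintegrity

Forest-extent maps say where forest is; they say nothing about whether a
stand is a tall, closed-canopy, old-growth forest or a short, recently
cleared regrowth. `forestintegrity` implements two raster indices that
score stand *quality* for the humid tropics, plus the lidar-based
procedure used to validate them, for landscape ecologists and
conservation planners working with 30 m classified rasters and airborne
lidar point clouds.

**SCI (Forest Structural Condition Index)** scores each 30 m cell 1–18
from three co-registered layers — canopy cover class (<25, 25–75,
>75–95, >95 %), canopy height class (0–5, >5–15, >15–20, >20 m) and loss
epoch (loss in 2013–2017, 2001–2012, or none since 2000). Recently
disturbed, short, or open cells score 1; tall closed-canopy undisturbed
stands score 18.

**FSII (Forest Structural Integrity Index)** discounts SCI by human
pressure. The Human Footprint score (HFP, 0–50) classes as Low
(weight 1, HFP < 4), Medium (5, 4 ≤ HFP ≤ 15) or High (10, HFP > 15):

```
FSII = SCI × 1 / (human pressure weight)      ∈ [0.1, 18]
```

**Validation pipeline**: vegetation lidar returns are normalized to
height above ground (k = 6 nearest ground returns, inverse-distance-
squared weights), heights > 70 m dropped, and foliage height diversity
computed per 30 m cell as the Shannon index of 1 m height bins,
FHD = −Σ pᵢ ln pᵢ, masking cells below 10 points/m². FHD grids are
bilinearly aligned to the SCI grid, samples restricted to cores of
homogeneous SCI patches (≥3×3 cells, 90 m perimeter buffer), and three
models compared by maximum-likelihood AIC: OLS, a transect random
intercept, and patch nested in transect.

A seeded synthetic generator produces patchy landscapes that invert
exactly under the classifier and point clouds whose per-class vertical
profiles have known closed-form FHD, so the whole pipeline is testable
without any external data.

## Worked example

```r
library(forestintegrity)

# a 24 x 24-cell synthetic landscape covering all 18 classes
ls <- generate_landscape(landscape_config(n_rows = 24, n_cols = 24,
                                          n_patches = 96, seed = 11))
sci <- compute_sci(ls$stack)
identical(sci$values, ls$truth$values)
#> [1] TRUE

fsii <- compute_fsii(sci, ls$stack$hfp)
range(fsii$values)
#> [1] 0.1 1.8   # the scene's single ~1 km HFP cell (38.3) classes High, weight 10

# lidar simulation -> FHD -> validation samples
cloud <- generate_point_cloud(ls$truth, canopy_profile_model(), seed = 11)
fhd   <- compute_fhd(filter_points(normalize_heights(cloud)), sci$spec)
cores <- extract_cores(label_patches(sci), min_cells = 4, buffer_m = 30)
samples <- build_samples(fhd, sci, cores)
summarize_fhd_by_sci(samples)
#> # A tibble: 5 × 4
#>     sci     n mean_fhd   sd_fhd
#>   <int> <int>    <dbl>    <dbl>
#> 1     1     2     1.20  0.00301
#> 2     4     2     1.86  0.00364
#> 3     7     1     2.30 NA
#> 4    11     1     2.76 NA
#> 5    14     2     3.08  0.00392
```

Mean FHD rises with SCI class — the qualitative signature the index is
built to carry — and with the default saturating profile model it
plateaus above class 14.

```r
s <- simulate_validation_samples(seed = 42)   # 10 transects x 20 patches x 9 cells
fits <- list(fit_ols(s),
             fit_random_intercept(s, "transect"),
             fit_random_intercept(s, "patch_in_transect"))
compare_models(fits)
#>          name                            formula     aic delta_aic r2_marginal r2_conditional  nobs
#> 1   ri_nested FHD = SCI + (1|transect/patch) + e -2546.2         0      0.8299         0.9812  1800
#> 2 ri_transect       FHD = SCI + (1|transect) + e -1040.6      1506      0.8300         0.9396  1800
#> 3         ols                      FHD = SCI + e   758.8      3305      0.8250         0.8250  1800
```

The nested random-effects model wins on AIC and conditional R², exactly
the ranking expected when observations are grouped within patches within
transects. `tidy()` and `glance()` expose coefficients and fit
statistics; `autoplot()` methods plot rasters, per-class SCI histograms,
FHD-vs-SCI samples and model comparisons.

A command-line front end wraps the same functions:

```sh
exec/forestintegrity simulate --out-dir demo --seed 1
exec/forestintegrity sci --cover demo/cover.tif --height demo/height.tif \
    --loss demo/loss.tif --out demo/sci.tif
exec/forestintegrity fsii --sci demo/sci.tif --hfp demo/hfp.tif --out demo/fsii.tif
```

Every output gets a `.provenance.json` sidecar recording inputs,
parameters, versions and seed.

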