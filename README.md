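# ehacube

Emerging hotspot analysis (EHA) of annual forest-loss rasters in R.

Tropical deforestation shifts in space and intensity over time, and a single
cumulative loss map hides that history. `ehacube` is for spatial ecologists
and conservation analysts who work with annual first-loss rasters (the
Global Forest Change loss-year coding: 0 = never lost, `v` = first loss in
year 2000 + `v`) and want to know, per location, *how* loss clustering
evolved: did it appear only last year, run uninterrupted at the end of the
record, intensify, persist, fade, flicker, oscillate through cold phases, or
end after a long history?

The pipeline:

1. **Space–time cube** — aggregate the loss raster onto an analysis grid
   (default 5-km bins) of per-year loss counts `x_{rct}`.
2. **Getis–Ord Gi\*** — for every space–time bin, the local statistic

   ```
   z_i = ( Σ_j w_ij x_j − X̄ W_i ) / ( S · sqrt( (n W_i − W_i²) / (n − 1) ) )
   ```

   with binary weights over a 10-km spatial neighbourhood and the current +
   previous `τ` years, and the global mean X̄ and SD S over all `n` masked
   bins. Bins with `z > 1.96` (α = 0.05) are hot, `z < −1.96` cold.
3. **Mann–Kendall** — per-location trend test (tie-corrected variance,
   continuity-corrected z) on the count series (or, optionally, the Gi*
   z series).
4. **Classification** — each location gets one of the eight EHA categories
   (new, consecutive, intensifying, persistent, diminishing, sporadic,
   oscillating, historical) or none; "persistent-class" rules use the
   floor(0.9·T) threshold, i.e. 16 of 18 annual steps.
5. **Protected-area overlay** — per-PA category shares, inside/outside
   totals, and distance-to-boundary profiles (GeoJSON polygons in, tibbles
   out).
6. **Driver attribution** — per-category covariate summaries (mean ± SEM),
   per-covariate Kruskal–Wallis tests, and an interpretable CART
   classification tree (Gini or cross-entropy splits) over elevation,
   slope, human footprint and distances to plantation features.

A first-class synthetic-scenario generator plants each category template as
a patch with known ground truth (with depletion-compensated hazards, so a
"persistent" patch really does produce flat expected counts under
first-loss semantics), which is how the whole pipeline is validated without
external data. Rasters travel as plain-text ESRI ASCII grids, vectors as
GeoJSON.

## Worked example

```r
library(ehacube)

sp <- scenario_spec(
  grid_rows = 80, grid_cols = 80, cell_size = 1000, n_years = 18,
  background_rate = 0.01, seed = 17,
  patches = list(
    planted_patch("persistent", 0.04, rows = c(11, 25), cols = c(11, 25)),
    planted_patch("new",        0.30, rows = c(51, 65), cols = c(51, 65))))

sim  <- generate_loss_raster(sp)        # loss raster + ground-truth labels
cube <- build_cube(sim$raster, bin_size = 5000)
res  <- run_eha(cube, eha_params(neighborhood_distance = 10000, tau = 1))
res
#> <eha_result> 252 analysis locations (counts trend series)
#>          new  consecutive intensifying   persistent  diminishing     sporadic
#>           27            0            0            5            0            7
#>  oscillating   historical         none
#>            0            0          213
```

The new patch and its 10-km neighbourhood light up as `new` (27 locations —
EHA deliberately smooths over the neighbourhood distance, so a burst flags
its surroundings too); the persistent patch core classifies `persistent`,
with a few edge bins degrading to `sporadic` at this pixel density.

```r
annual <- annual_loss_series(sim$raster)
attr(annual, "total_km2");  attr(annual, "mean_km2_yr")
#> [1] 1283
#> [1] 71

category_composition(res)
#> # A tibble: 3 × 3
#>   category       n   pct
#>   <chr>      <int> <dbl>
#> 1 new           27  69.2
#> 2 sporadic       7  17.9
#> 3 persistent     5  12.8
```

So this synthetic landscape lost 1,283 km² over 18 years (a truncated mean
of 71 km²/yr), and of its category-bearing locations 69.2% are `new`.
`autoplot(res)` draws the category map; `tidy(res)` returns the
per-location diagnostics (hot/cold counts, terminal run, trend z and p);
`run_pipeline(eha_config(...))` runs everything including overlay and
drivers and writes the artifact files (category map, CSVs, decision tree,
JSON report).

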