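---
title: "Emerging hotspot analysis of annual forest-loss rasters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emerging hotspot analysis of annual forest-loss rasters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehacube)
```

`ehacube` implements emerging hotspot analysis (EHA) for annual first-loss
rasters such as the Global Forest Change loss-year product: a pixel is coded
0 if it never lost forest over the record and `v` (1..18 by default) if its
first detected loss fell in year `2000 + v`. EHA asks, for every place on the
landscape, not just *whether* loss clusters there but *how that clustering
behaved through time*, and names the answer with one of eight pattern
categories (new, consecutive, intensifying, persistent, diminishing,
sporadic, oscillating, historical). This vignette documents the model, its
tunable parameters, the synthetic-data generator that underwrites the test
suite, and the numerical and design choices the implementation makes where
the method description leaves the design open.

## The model

### Space–time cube

The loss-year raster is aggregated onto a coarser analysis grid of square
*bins* (default edge 5,000 m). For bin location $(r, c)$ and year $t$ the
cube stores the count $x_{rct}$ of pixels whose first loss fell in year $t$.
Partial bins at the grid edge are retained with their true pixel counts. A
location enters the analysis mask if it recorded at least one loss event over
the whole record (`mask_mode = "any-loss"`); this mirrors cube-from-points
behaviour in which event-free locations carry no bins, and it is exposed as a
switch (`"all"`) because either convention is defensible. The total number of
masked space–time bins is $n$.

The method never leaves a local metric coordinate system: all distances are
Euclidean, which is the appropriate reading for a "neighborhood distance"
parameter quoted in kilometres. Reprojection and geodesy are out of scope.

### Getis–Ord Gi*

For every masked bin $i$ the local statistic is

$$ z_i \;=\; \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
  {S \sqrt{\left(n W_i - W_i^2\right)/(n-1)}},
  \qquad
  S = \sqrt{\tfrac{1}{n}\sum_j x_j^2 - \bar{X}^2}, $$

with binary weights $w_{ij} \in \{0, 1\}$ over a space–time neighbourhood,
$W_i = \sum_j w_{ij}$, and $\bar{X}$, $S$ the mean and standard deviation over
all $n$ masked bins of the cube (global standardization; a per-slice
background is a possible alternative reading, and the global one is what a
cube-wide "counts in a bin relative to its neighbourhood" comparison
implies). A bin is *hot* when $z_i > z_{crit}$ and *cold* when
$z_i < -z_{crit}$, with $z_{crit} = \Phi^{-1}(1 - \alpha/2)$, i.e. 1.96 at
the default $\alpha = 0.05$. A constant cube has $S = 0$ and is defined to
yield all-zero z and all-neither labels rather than an error.

The neighbourhood combines a spatial radius (default 10,000 m between bin
centroids, binary weights with no kernel decay — the simplest reading of a
stated neighbourhood distance) and a temporal window of the current and the
$\tau$ *previous* time steps (default $\tau = 1$), clipped at the start of
the record. The backward-looking window is a deliberate choice. A symmetric
window would let the statistic at year $t$ borrow counts from year $t+1$,
which has two bad consequences: the final year's statistic would be defined
differently from every other year's (there is no future data there), and a
single terminal burst of loss would also light up the pre-final year,
making a "hotspot that is hot only in the final step" — the *new* category —
essentially unobservable. With the causal window, an interior bin at
$t \ge \tau + 1$ has $13 \times (\tau + 1)$ neighbours at the default
5,000-m bins (13 spatial offsets within 2 bin widths, times the window
length); at $t = 1$ the window clips to the single current slice.

### Mann–Kendall trend

Each location's temporal trend is tested with the Mann–Kendall statistic
$S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)$, tie-corrected variance

$$ \mathrm{Var}(S) = \frac{n(n-1)(2n+5) - \sum_g t_g(t_g-1)(2t_g+5)}{18}, $$

continuity-corrected normal deviate and two-sided p-value. Under no trend
the expected z is 0. The normal approximation is used throughout (series
shorter than 4 steps are rejected); no Monte-Carlo p-values, matching a
workflow that reports z and p directly.

Which series should the trend run on? Category definitions speak of "the
intensity of clustering ... in each time step", which suggests the Gi* z
series, but also of the trend "in each bin", which suggests the raw counts.
Both are implemented. The *default* (`trend_on = "counts"`) is the raw
per-location count series, for a statistical reason: with $\tau \ge 1$ the
Gi* windows of adjacent years share count data, so the z series is serially
correlated by construction (roughly MA(1) with lag-1 correlation near 0.5 at
$\tau = 1$), and the Mann–Kendall test — whose null assumes exchangeability —
then flags spurious trends at a multiple of the nominal rate. The raw counts
are serially independent under the first-loss process, so the trend test
keeps its level, which matters most for the *persistent* category (defined
by the *absence* of a significant trend). `intensity_trend()` exposes the
z-series reading directly, and `trend_on = "zscore"` switches the pipeline
to it.

### The eight categories

With $T$ steps, the persistence threshold is
`min_hot_steps(T, hot_fraction)` $= \lfloor 0.9\,T \rfloor$ hot steps, which
for $T = 18$ gives 16 — the "16 of the 18 years" operationalization. (The
category prose says "more than ninety percent", which 16/18 = 88.9% does not
satisfy; the floor-based reading is the one that reproduces the printed 16
and is used consistently.) The classifier applies the first matching rule:

1. **new** — final step hot, and exactly one hot step ever;
2. **consecutive** — final step hot, an uninterrupted terminal hot run of at
   least 2 steps, no hot step before that run, fewer than `min_hot_steps`
   hot steps in total;
3. **intensifying** — final step hot, at least `min_hot_steps` hot steps,
   significantly increasing trend;
4. **diminishing** — final step hot, at least `min_hot_steps` hot steps,
   significantly decreasing trend;
5. **historical** — final step *not* hot, at least `min_hot_steps` hot
   steps;
6. **persistent** — at least `min_hot_steps` hot steps, no significant
   trend;
7. **oscillating** — final step hot, at least one cold step ever, fewer
   than `min_hot_steps` hot steps;
8. **sporadic** — final step hot, no cold step ever, fewer than
   `min_hot_steps` hot steps;
9. **none** otherwise.

Three placements in this order are design decisions rather than transcription:

* *historical before persistent.* The two definitions overlap for a location
  hot in ≥ 90% of steps but not at the end, with no significant trend.
  Historical's defining clause is "the most recent time period is not hot",
  so it must win that overlap; testing it first achieves this without
  changing any other outcome.
* *new requires exactly one hot step; consecutive requires a terminal run of
  at least two with no earlier history.* This separates the two "never been
  a hotspot before" clauses cleanly.
* *sporadic requires a hot final step.* Its prose omits this, but without it
  sporadic would swallow sequences the historical definition describes.

Cold-spot mirror categories are intentionally not emitted — only hotspots of
deforestation are of interest — and cold labels are consumed solely by the
oscillating rule. No multiple-testing correction is applied across bins,
matching the reference workflow.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `bin_size` | 5,000 | m | analysis bin edge. The reference analysis states its 10-km neighbourhood but not its bin size; 5,000 m puts 13 bins inside the neighbourhood and is exposed as a parameter. |
| `neighborhood_distance` | 10,000 | m | spatial neighbourhood radius between bin centroids |
| `tau` | 1 | steps | temporal window: current + `tau` previous years |
| `alpha` | 0.05 | — | two-sided level for both Gi* labels and the trend |
| `hot_fraction` | 0.90 | — | persistence threshold; `floor(0.9 * 18) = 16` |
| `mask_mode` | "any-loss" | — | which locations carry bins |
| `trend_on` | "counts" | — | trend series; `"zscore"` for clustering intensity |

## The synthetic-data generator

External inputs (Landsat-derived loss, protected-area polygons, SRTM
terrain, the 1-km human-footprint index, plantation locations) are not
reproducible at desk scale, so the package generates synthetic stand-ins
with known ground truth; every downstream stage is validated against that
truth.

### Planted space–time patterns

A scenario is a pixel grid (defaults: 120 × 120 pixels, 1,000-m cells, 18
years), a background per-pixel first-loss probability $p_0$, and a set of
planted patches, each carrying one of the eight category templates (plus a
pure-cold template), a footprint and an amplitude. Templates are
deterministic intensity profiles: *new* is on only in the final year;
*consecutive* in the final $\lfloor 0.3T \rfloor$ years; *intensifying*
ramps linearly $t/T$; *diminishing* ramps $\,(T-t)/(T-1)$ to zero;
*persistent* is always on; *sporadic* is on in off-and-on blocks (under 90%
of years, final year on); *oscillating* alternates on-blocks with
*suppressed* blocks in which the patch's loss probability is forced to zero
— below the surrounding background, which is what a Gi* *cold* bin needs;
*historical* is on for an initial run covering the persistence threshold
(16 of 18 years) and off for the final two. The two-year off-tail is
deliberate: with $\tau = 1$ the final year's window still contains the
previous year, so a single off year cannot make the final step "not hot".

### Depletion-compensated hazards

A pixel can be lost at most once (first-loss semantics), so under a constant
hazard the pool of not-yet-lost pixels drains and every sustained template
would produce a mechanically *decreasing* count series — a persistent patch
would classify as diminishing by construction. The generator therefore
treats the template as a target for the *expected newly-lost fraction of the
original pixels*:

$$ r_t = p_0 (1 - p_0)^{t-1} \cdot [\text{not suppressed}_t]
       + a \cdot \text{profile}_t, $$

and solves the per-year hazards recursively, $h_t = r_t / s_{t-1}$,
$s_t = s_{t-1} - r_t$. Off years then match the depleting background
exactly, suppressed years have zero loss, and a persistent patch's expected
counts stay flat. Scenarios whose targets would exhaust the pixel pool
($h_t > 1$) are rejected with an error — amplitudes and durations trade off
against each other under a hard budget of 100% cumulative loss, which is
itself a faithful property of first-loss data: an 18-year "intensifying to
very high rates" pattern is only feasible up to the point where the forest
runs out.

### The reference scenario and its power analysis

`demo_scenario()` fixes the validation conditions: a 1,120 × 1,120-pixel
grid of 500-m cells (a 560-km square), 5,000-m bins (112 × 112 locations,
100 pixels per bin), $p_0 = 0.0075$ per pixel-year (≈ 12.7% background loss
over 18 years, a realistic frontier-landscape level), and eight
well-separated 5 × 5-bin patches, one per template. The choices follow from
detection arithmetic rather than trial and error:

* **Signal.** For a patch bin with excess per-pixel rate $\Delta p$ over
  background, $z \approx \sqrt{W m}\,\Delta p / (S/\sqrt{m})$ with $m$
  pixels per bin: detectability grows with $\sqrt{m}$, so 100 pixels per bin
  lets modest amplitudes (0.03–0.30, scaled per template so cumulative
  targets stay below 1) clear $z_{crit}$ by factors of 3–10.
* **Cold bins.** A suppressed bin is cold only if its whole neighbourhood
  sum falls far below $n\bar{X}$ in units of $S$; this requires a
  non-trivial background ($p_0$ not too small) and a patch wide enough that
  the 2-bin neighbourhood of its core lies inside the suppressed area —
  hence 5 × 5-bin patches.
* **Background false rate.** Bins within one neighbourhood radius of a
  patch are genuinely elevated (EHA smooths over 10 km — that halo is
  correct behaviour, not error), so the grid is large enough that halo plus
  noise stays a small fraction of background locations.
* **Separation.** Patch edges sit ≥ 5 bins apart, beyond twice the
  neighbourhood radius, so no patch contaminates another's labels.

One planted pattern is expected *not* to round-trip: the diminishing
template ramps to zero, so its final step is indistinguishable from
background and the diminishing rule — which requires a hot final step —
cannot fire; those locations classify historical (or drop below the
persistence count and fall to none). This is a real identifiability limit of
the category system on first-loss data, not a detector defect, and the
validation criteria require only that at least six of the eight templates
are majority-recovered, with persistent, new and historical recovered
exactly at patch cores.

### What the generator does not emulate

Cloud/shadow artifacts, reflectance, regrowth, the tree-cover baseline,
spatially autocorrelated background hazard, and real road-network topology
(roads are straight chords; footprint decays exponentially from them with a
10-km e-folding length, clipped to the 0–50 index range; elevation is a sum
of Gaussian bumps; plantations are uniform Poisson points). Passing tests
therefore demonstrate that the statistics, classifier and overlays do what
they claim on data whose generating process is known — not that any
particular real landscape will show a given category mix.

## Covariates, group tests, trees

Driver attribution works at the analysis-location level (the method's
sampling unit is one bin location; per-pixel units would pseudo-replicate
within bins). Elevation is averaged to the analysis grid and slope computed
from it with Horn's 3 × 3 method (edge windows clamped); the coarse
footprint index is resampled by nearest neighbour; distances to plantation
features are straight-line ("Near"-style) distances from bin centroids,
computed against points or polygon vertices/edges. Kruskal–Wallis (the
tie-corrected H with a $\chi^2_{k-1}$ approximation, via
`stats::kruskal.test`; a no-variation input returns H = 0, p = 1) runs once
per covariate across category groups.

The classification tree is authored in the package: greedy binary
partitioning over midpoint thresholds minimizing Gini (default) or
cross-entropy — both criteria are implemented since the method description
names both without choosing. Conventions worth stating: cases go left iff
`value < threshold` (so a rule "footprint ≥ 12" labels the right child);
impurity ties break to the lowest covariate index, then lowest threshold;
stopping is at `max_depth` 4 (printed reference trees are shallow),
`min_leaf` 5% of the sample, or zero gain; leaves carry the class
distribution and their percentage of the evaluated data, and the indented
text rendering prints those percentages. `rpart` is used in the test suite
as an independent cross-check of a planted split threshold, never as the
implementation.

## Overlay conventions

A location belongs to a protected area iff its bin centroid falls inside the
polygon (fractional-area weighting would invent sub-bin information the
cube does not have; this is logged as a limitation for PAs whose boundaries
slice bins). Overlapping PAs resolve to the first listed, with a warning.
Per-PA shares are percentages over the PA's covered analysis locations —
a PA covering no location reports undefined (NA) shares, not zeros — and
island-level summaries count category-bearing locations inside versus
outside any PA. The boundary profile bins signed centroid-to-boundary
distances (negative inside) into fixed-width rings, the standard way to
examine boundary-concentrated loss ("neighbourhood leakage").

## Numerical choices and degenerate inputs

* Mean annual loss rates are reported in km² with the mean optionally
  truncated toward zero (67,104/18 = 3,728 exactly; 88,504/18 = 4,916.9 →
  4,916 — truncation, not rounding, reproduces headline rates).
* Raster I/O uses the plain-text ESRI ASCII grid with a JSON sidecar for
  the CRS tag; vector I/O uses GeoJSON. Both are exact for integer grids.
* Points exactly on a polygon boundary follow `mgcv::in.out`'s convention;
  bin centroids sit on a half-cell lattice, so ties require deliberately
  degenerate geometry.
* All-zero cubes produce an empty mask and an empty category map; a cube
  with fewer than two masked locations is rejected for Gi*; constant cubes
  produce all-neither labels; empty feature sets are rejected for distance
  maps (distance to nothing is undefined).
* Every simulation consumes randomness only through the scenario seed, and
  identical configurations reproduce byte-identical artifacts.

## Problem sizes used in validation

The test-suite and acceptance runs use: 100 random 6 × 6 × 4 cubes checked
bin-for-bin against a brute-force Gi* evaluation (tolerance 1e-9); 10,000
iid length-18 series for the Mann–Kendall type-I level; the 112 × 112-bin
reference scenario for planted-category recovery; and n = 2,000 samples
with 5% label noise for recovering a planted "footprint ≥ 12" tree split
within ±0.5. These sizes make the brute-force oracles exact companions of
the production code while keeping a full validation run in the
tens-of-seconds range on one CPU.

## Known limitations

* The diminishing category is unidentifiable for patterns that genuinely
  ramp to zero (see above).
* Gi* p-values are normal-approximation p-values on count sums; for very
  sparse cubes the discreteness is visible in the tails, and no
  multiple-testing correction is applied across bins.
* The z-series trend mode inherits serial correlation from overlapping
  windows; it is provided for fidelity to the "intensity of clustering"
  reading, with the counts mode as the level-preserving default.
* Centroid-membership overlays quantize PA shares at bin resolution.
* The polygonized category-map export does not dissolve shared edges.
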