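---
title: "Ecosystem quality assessment from vegetation indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecosystem quality assessment from vegetation indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eqiscope` implements an objective, automatic assessment of vegetation-based
ecosystem quality from three remote-sensing indicators — leaf area index
(LAI, dimensionless), fractional vegetation cover (FVC, a fraction in
[0, 1]) and gross primary productivity (GPP, mass carbon per area per
time) — harmonized on one analysis grid. This vignette describes the model,
its assumptions, the tunable parameters, the synthetic test data, and the
numerical and design choices, in that order.

## The model

**Harmonization.** Each indicator arrives as a sub-annual raster time
series (quarterly LAI; 8-day FVC and GPP). Series are composited to annual
grids by the maximum value composite (MVC): the per-pixel maximum over all
slices with a valid observation. MVC favors the peak-growth, least
contaminated observation and is the standard compositing rule for
vegetation index series. Finer-resolution inputs are then brought onto the
analysis grid (defined by the coarsest input, the 1 km LAI/LULC geometry)
by nearest-neighbor resampling. Nearest neighbor keeps original
radiometry — no new values are invented — at the cost of sub-cell
positional error, which is the conventional trade-off when harmonizing
categorical and continuous layers together.

**Stratification.** Quality is always judged relative to what is
attainable locally. The study area is partitioned into strata by crossing
eco-geographical zones (an input cartographic product) with six vegetation
ecosystem types reclassified from first-level land use/land cover:
cultivated land, forest, grassland, shrub, wetland and tundra.
Non-vegetation is masked. A pixel missing any indicator is excluded from
every stratum statistic (complete-case rule), because the composite index
needs all three standardized densities at a pixel.

**Indicator relative density (IRD).** For year $i$, zone $j$ and type $k$,

$$\mathrm{IRD}_{i,j,k} = \frac{F_{i,j,k}}{F_{\max\,i,j,k}},$$

where $F_{\max}$ is the stratum's reference value: by default the stratum
maximum of the indicator in that year. With maximum references the IRD lies
in [0, 1], every stratum attains 1, and the density is invariant to
positive rescaling of an indicator within a stratum — so strata with very
different physical magnitudes (tundra vs. rainforest) become comparable.

**Standardization.** The three IRD fields have different spreads, so each
is z-scored, $Z = (x - \bar{x})/\sigma$, over all valid pixels of the study
area, per indicator and per year. $\sigma$ is the population
(divide-by-$n$) standard deviation; at raster sample sizes the distinction
from the $n-1$ variant is far below every tolerance used here, but the
choice is fixed and tested. The estimated parameters are returned and
serialized so that a stored standardization can be re-applied
bit-identically.

**PCA weighting.** Indicator weights are estimated from the data rather
than from expert judgment. With $X$ the $m \times 3$ matrix of standardized
densities at complete-case pixels, the correlation matrix $R$ is
eigendecomposed, $\alpha_1 \ge \alpha_2 \ge \alpha_3$, with contribution
rates $e_i = \alpha_i / \sum\alpha$. The smallest $p$ components whose
cumulative contribution reaches $\rho$ (default 0.85) are retained, each
indicator is scored

$$\gamma_i = \frac{\sum_{j \le p} |c_{ij}|\, e_j}{\sum_{j \le p} e_j},$$

and weights are normalized, $\omega_i = \gamma_i / \sum\gamma$. The
loadings enter in absolute value: signed loadings can produce negative
weights, which would break the convex-combination reading of the index
(weights nonnegative, summing to 1). The signed variant remains available
(`signed_loadings = TRUE`) for sensitivity analysis. Weights are estimated
per epoch and averaged arithmetically across epochs, then renormalized.

**The index and its classification.** The ecosystem quality index is the
weighted sum $\mathrm{EQI} = \sum_i \omega_i Z_i$ per pixel. Pooled values
of all epochs are classified into five levels (poor, low, moderate, good,
excellent) by exact Fisher–Jenks natural breaks — the partition of the
sorted values into contiguous classes minimizing the within-class sum of
squared deviations. Pooling the epochs yields one break set, hence level
maps that are directly comparable across years. Classification intervals
are lower-open and upper-closed: a value equal to a break belongs to the
lower class. The preset `"brr-2016-2020"` ships the published break set
(−0.97, −0.25, 0.44, 1.19) so published level maps can be reproduced from
any EQI grid without re-running Jenks.

**Change.** Two-epoch change is the per-pixel difference
$\Delta\mathrm{EQI} = \mathrm{EQI}_{y_2} - \mathrm{EQI}_{y_1}$, classified
with the adopted ±0.05 significance thresholds:
$\Delta \le -0.05$ decreased, $-0.05 < \Delta \le 0.05$ no change,
$\Delta > 0.05$ increased. Area shares of the three classes are tabulated
for the whole study area, per zone, per ecosystem type and per stratum,
with both denominators (share of total study area, share within the group)
because published proportion figures use either convention. The same
tabulation applied to level grids gives level-share tables; there is no
separate code path.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `reference_method` | `"max"` | stratum reference; `"percentile"` with `q` (default 0.99) guards against single-pixel outliers |
| `standardization` | `"per_year"` | re-estimate z-parameters per epoch; `"shared_baseline"` applies epoch-1 parameters to all epochs |
| `rho` | 0.85 | cumulative contribution-rate threshold for retained components |
| `breaks` | `"jenks"` | five-level classification; a preset name or numeric cut points fix the breaks |
| `k` | 5 | number of quality levels |
| `jenks_sample_size` | 1e5 | subsample cap for Jenks on large rasters (seeded, recorded) |
| `change_thresholds` | ±0.05 | significance band on ΔEQI, in EQI (z-scale) units |
| `weighting` | `"pixel"` | area convention for tables; `"cosine"` weights by cos(latitude) on geographic grids |

Every default is the published choice where one exists; the rest are
conventional. `weights_in` bypasses estimation entirely, e.g. with the
published two-year weights (0.3333, 0.2626, 0.4041).

Two options deserve comment because the underlying definitions are open to
reading. First, the standardization population: z-scoring is done globally
(all valid pixels, per indicator, per year) rather than per stratum,
because the index mixes strata and one global Jenks classification is
applied to the pooled index — per-stratum z-scores would destroy
cross-stratum comparability. Second, cross-year comparability: per-year
standardization is the literal reading (references are per-year), but it
lets a change in one region shift everyone's z-scores slightly through the
re-estimated mean and spread; `"shared_baseline"` exists for users who
want ΔEQI free of that re-standardization drift.

## The synthetic scenario generator

Real continental-scale indicator products cannot ship with a package, so
`generate_scenario()` fabricates datasets with the statistical structure
the method assumes, and nothing else. Its defaults are the package's
standing study conditions: a 200 × 200 analysis grid at 1 km analog cell
size; 10 Voronoi-contiguous eco-geographical zones; a 150-patch LULC
mosaic over the six vegetation types plus water/barren; quarterly LAI at
analysis resolution and 46-slice (8-day) FVC/GPP at half the cell size, so
the resampling path is exercised; strong positive inter-indicator
correlation (0.7–0.8); 2% nodata in blobs; and two rectangular planted
change regions with offsets ±0.5 on the EQI scale.

Construction: per fine pixel, indicator = stratum mean × zone factor +
spread × Gaussian driver, where the drivers mix a smooth shared spatial
field with a Gaussian copula whose correlation is adjusted so the total
per-pixel correlation hits the target. Marginals use plausible physical
magnitudes (LAI-like in [0, 7], FVC-like in [0, 1], GPP-like in
[0, 3000]) so unit heterogeneity genuinely stresses the standardization;
the approach to each ceiling is a smooth saturation rather than a hard
clamp, because a clamp would pile an atom of probability at exactly the
reference value. Sub-annual slices are the annual field scaled by a
seasonal profile whose peak slice is left exact, so MVC provably recovers
the annual field. The second epoch adds small temporal noise (2% of each
pixel's IRD-scale spread — vegetation fields are highly persistent across
nearby years) plus the planted offsets.

Planted offsets are calibrated on the index scale: a shift of
$\delta \cdot \mathrm{sd}(\mathrm{IRD}) \cdot F_{\max}$ in indicator units
moves that pixel's standardized density by about $\delta$. Two details
keep the construction honest under max references. Planted improvements
are capped at the stratum's epoch-1 reference as the analysis grid will
see it (quality cannot exceed the regional best), so gains do not inflate
the epoch-2 references and thereby depress everyone else's density; and
each stratum's reference pixel keeps its epoch-1 value, so planted
declines cannot deflate the reference and spuriously inflate the rest of
the stratum. Both effects are real behaviors of max-reference
normalization — the generator pins them down so that the sign of planted
change is known by construction.

What the generator does **not** emulate: sensor radiometry, cloud and QA
artifacts, geolocation error, mixed pixels, LULC change between epochs, or
trend structure over more than two epochs. Passing tests therefore
demonstrate correctness of the method's arithmetic and its documented
conventions on data with realistic statistical structure — not robustness
to real-product artifacts.

## Numerical choices

- **Jenks** is the exact Fisher dynamic program over sorted distinct
  values with multiplicity, not the heuristic reallocation variant; the
  optimal-split monotonicity of the interval SSE cost admits a
  divide-and-conquer filling of the table, so exact classification of the
  default 1e5-value sample is routine. Among equal-cost optima the
  partition whose lowest class is smallest wins; tests verify equality
  with exhaustive search over all partitions for small inputs.
- **Eigendecomposition** uses the symmetric solver; any converged
  symmetric eigensolver yields the same decomposition, which tests verify
  against characteristic-polynomial closed forms for 2 × 2 and 3 × 3
  matrices. Each eigenvector is scaled so its largest-magnitude element is
  positive — irrelevant under absolute loadings but fixed so the reported
  loading matrix is reproducible. With tied eigenvalues the importance
  scores are not invariant to rotation within the tied block; the
  symmetric cases covered by tests (identity, equicorrelation with one
  retained component) are the ones with a rotation-free answer.
- **Loading scale:** the importance formula is implemented on unit
  eigenvectors (`loading_scale = "unit"`); scaling columns by
  $\sqrt{\alpha_j}$ (`"sqrt_eigenvalue"`, conventional component loadings)
  is available, and with contribution-rate weighting the two give
  different mixtures. The package does not guess which was intended
  upstream; it documents both and defaults to unit.
- **Nearest-neighbor ties** (an output center equidistant from two source
  centers, which happens systematically in integer-ratio resampling) go to
  the smaller row, then smaller column index. Fractional source indices
  within 1e-9 of an integer are snapped before the tie rule, so
  floating-point jitter cannot flip a tie.
- **Alignment tolerance:** grids are "aligned" when shapes and crs match
  exactly and geotransform terms agree within 1e-9 map units.
- **On-disk format** is the ESRI ASCII grid with a `.prj` sidecar carrying
  the crs tag: a plain-text, universally readable interchange raster.
  Values are written with `%.17g`, so a write-then-read round trip is
  bit-exact for doubles. Class grids use the same format (small integers
  print compactly). No reprojection is implemented anywhere: inputs must
  share a crs, and a mismatch is an error rather than a silent transform,
  because resolution — not projection — is what this method harmonizes.
- **Degenerate inputs** fail loudly and early: non-positive stratum
  references (the density would be undefined), zero-variance
  standardization populations, constant PCA columns, fewer distinct values
  than classes, inverted thresholds, unmapped LULC codes, misaligned
  grids.

## Test problem sizes

The test suite builds every fixture in code. Unit tests run on toy grids
(up to 50 × 50) where brute-force oracles are feasible; the deeper checks
use a 200 × 200 two-epoch scenario for planted-change recovery, 500
randomized Jenks instances against exhaustive search, 100 random
correlation matrices against closed forms, and 20 replicates of the
weight-ordering construction at 1e5 observations. These sizes were chosen
so the whole suite exercises every path at full fidelity while remaining
quick enough to run habitually.

## Known limitations

- Max references are outlier-sensitive by construction; one anomalous
  pixel redefines a stratum's reference. The percentile option mitigates
  this but departs from the strict definition.
- Per-year standardization couples ΔEQI to global distribution shifts
  between epochs (see `"shared_baseline"` above).
- The eco-geographical zone map is an input, not derived; zone labels are
  treated as opaque identifiers.
- Quarterly and 8-day calendars are composited independently per
  indicator; no cross-calendar alignment is attempted, since the maximum
  composite is calendar-internal.
- Only two-epoch change is supported; trend analysis over longer series is
  out of scope, as are attribution analyses.
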