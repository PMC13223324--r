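---
title: "Methods: ecosystem-service models, synthetic landscapes, and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecosystem-service models, synthetic landscapes, and driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoserv)
```

`ecoserv` quantifies five ecosystem services on categorical land-use rasters,
accounts for land-use change, and attributes regional service variation to
land-use composition. This vignette is the package's record of the science
behind each stage: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## The landscape model

All rasters are plain matrices with a cell size in km (`es_raster`); cell
`[1, 1]` is the north-west corner and areas always come from
`cell_size_km^2`, never from projection math — synthetic landscapes carry no
real CRS. The seven-class legend (forest, grassland, water, urban/rural,
unused, paddy, dry cropland) is fixed; every per-class parameter table is
validated against it on read.

## Service models

### Carbon sequestration

Pure bookkeeping: each class carries four pool densities (above-ground,
below-ground, soil, dead organic matter, t/hm²) and a cell's stock is their
sum times the cell area. The model assumes densities are constant within a
class across the domain — the standard assumption of land-cover carbon
accounting, and its main limitation: spatial heterogeneity within classes is
invisible. Because the model is linear in class areas, a closed-form tabular
path (`carbon_class_totals()`) is exposed beside the raster path; the test
suite holds them to 1e-9 relative agreement, which also guards the unit
conversions (1 km² = 100 hm²).

### Annual water yield (Budyko–Fu)

Yield is precipitation minus actual evapotranspiration per cell, with AET
from the Fu form of the Budyko curve:

$$\frac{AET}{P} = 1 + \frac{PET}{P} - \left(1 + \left(\frac{PET}{P}\right)^{\omega}\right)^{1/\omega},
\qquad \omega = \frac{Z \cdot AWC}{P} + 1.25.$$

`PET = Kc·ET0` uses the per-class crop coefficient; `AWC = PAWC ×
root_depth` (mm) with an optional root-restricting-depth cap. The printed
source formula for yield contains a dimensionally inconsistent "1 +" term;
we implement the standard InVEST annual-water-yield formulation above, which
the source itself says it follows. Key properties, all tested: `0 ≤ AET ≤ P`,
exact water balance `Y + AET = P`, monotonicity in `P` and `PET`.

Tunables: the seasonality constant `Z` (dimensionless, default 5 — the
source never states it; 5 is a mid-range value for monsoonal climates) and
the ω offset 1.25 (the Fu-curve lower bound). Open-water and built-up cells
(root depths 10 and 1 mm) get near-zero AWC, hence ω near 1.25; the generic
formula is applied to them rather than any special open-water clamp, since
the source gives no such rule.

### Potential soil erosion (USLE)

`A = R·K·LS·C·P_c` per cell, with `C` (cover) and `P_c` (practice) looked up
per class and `R`, `K`, `LS` as grids. Erosivity uses the monthly
power-sum estimator

$$R = 1.2157 \sum_{i=1}^{12} 10^{\,1.5\,\lg(P_i^2/P) - 0.0818}
    = 1.2157 \cdot 10^{-0.0818} \sum_i \left(\frac{P_i^2}{P}\right)^{1.5},$$

with the annual total recomputed from the months (a supplied annual grid is
only a consistency check). Zero-precipitation months contribute zero; an
all-dry year gives `R = 0`. The estimator is homogeneous of degree 1.5 —
scaling all months by `c` scales `R` by `c^1.5` — which the tests use as an
algebraic oracle. Erosivity units are treated as opaque-but-consistent: the
source's printed unit string is garbled, so only relative and product
quantities are asserted. `LS` is consumed as an input raster; the
`ls_from_slope()` helper (two-piece slope-steepness form with the cell size
as flow-path length) exists for users starting from slope maps, but the
pipeline never requires it, because the source describes no DEM processing.

This is *potential* (gross) soil loss: no sediment delivery ratio, routing,
or channel processes.

### Habitat quality

Four land-use classes act as threats (urban/rural, unused, paddy, dry) with
weights and maximum impact distances. Influence of a threat at distance `d`
decays linearly, `max(0, 1 − d/d_max)`, or exponentially,
`exp(−(2.99/d_max)·d)`; both are truncated at `d_max`. Per threat, a cell's
exposure is the influence of the **nearest** source cell (max-combine).
Summing over all source cells is available (`combine = "sum"`) for
sensitivity analysis, but max-combine is the default because summation grows
without bound on dense threat maps and makes `D` scale with patch size
rather than proximity. Threats combine as a weighted sum, giving the
degradation degree `D`; quality is

$$Q = H_j\left[1 - \frac{D^z}{D^z + k^z}\right]$$

with suitability `H_j`, exponent `z = 2.5` (a conventional default; the
source calls `z` only a normalisation constant), and half-saturation `k`
set to half the realised maximum degradation — so `Q = H/2` exactly where
`D = k`, a property the tests pin. Both `D` and `k` are raised to `z`; the
source's rendering of the exponent placement is ambiguous and this is the
convention of the model family it cites. `k` is recomputed per run by
default (matching the stated rule); pass an explicit `k` to compare maps
across epochs on a common scale — the pipeline does not fix it, so each
epoch's map is normalised to its own worst degradation, which is how the
stated rule behaves. The accessibility modifier of the fuller formulation is
fixed at 1 (no protected-area layer). Linear decay is the default; the
source is silent, and linear is the convention's default for these threat
types.

### Food-material supply (equivalent factors)

The two provisioning services analysed — food production and raw
material — are valued per class as `equivalent × E0` with
`E0 = 1505.8` Yuan/hm², taken as a parameter (its derivation from grain
cost-benefit compilations is out of scope). The combined coefficient is the
**sum of the two components**, not the independently printed combined row,
because that row disagrees with its own components by 1 Yuan for paddy and
forest (source-side rounding); the printed row ships as an alternative
fixture (`es_esv_coefficients(combined = "printed")`). A region of pure dry
cropland therefore values at exactly 18.82 × 10⁴ Yuan/km², which the
acceptance suite checks against the valuation path.

## Land-use accounting

Transfer matrices are oriented rows = earlier year, columns = later year;
cells nodata in either year are dropped symmetrically so row/column
marginals equal the class areas of each input on the shared mask and the
grand total is conserved exactly. Percent change is undefined (NA) on a zero
baseline. Full precision is kept internally; display rounding is the
caller's business.

## The synthetic landscape: a stated world

The generator emulates the structure the analysis assumes, not any real
geography:

- **Composition**: default class proportions are the 1990 shares of a
  ~243,000 km² cropland-dominated basin (dry 50.1%, paddy 19.7%, urban
  11.7%, forest 9.1%, grassland 4.2%, water 4.9%, unused 0.3%).
- **Pattern**: one box-blurred Gaussian noise field is ranked and sliced at
  the cumulative class proportions. Realised counts match the request to
  within one cell, patches are spatially autocorrelated (Moran's I > 0 on
  the 4-neighbour lattice), and identical seeds give bit-identical grids.
  The price of this construction is that classes occupy ordered bands of
  one latent field, so class adjacency structure is stylised.
- **Change**: per decadal step, conversion rules move a stated fraction of
  a source class to a target, preferring cells that touch existing target
  patches (accretive urban growth). Defaults were set once from the
  emulated basin's 1990→2020 accounting (urban +32% over three steps fed by
  dry and paddy land, grassland −27%, unused −78%, water +16%) and are not
  tuned thereafter.
- **Climate**: annual precipitation is a linear north–south gradient
  (default +1 mm/km southwards) around an exact domain mean of 992.9 mm,
  plus smooth east–west variability only — keeping row means strictly
  monotone along the gradient axis and the domain mean exact by
  construction. Months split the annual total by a wet-summer profile
  (~58% in May–September). Reference ET carries the opposite (drier-north)
  gradient. One climate stack is generated per epoch (seeded off the epoch
  index); multi-year averaging within epochs is left to the user.
- **Regions**: 29 contiguous regions from seeded multi-source flood fill —
  contiguity and exhaustiveness are guaranteed by construction and verified
  by a connected-components test.
- **Soil/terrain**: smooth log-normal-ish `K` (around 0.035) and `LS`
  (around 1.5, skewed toward plains) and `PAWC` in [0.08, 0.22] —
  magnitudes a soil survey of an alluvial basin would report.

What a green test on this world establishes: the algebra, conservation
properties, units, and statistical machinery of the pipeline. What it does
not establish: the absolute service totals of any real region — those
depend on real rasters that are deliberately out of scope, so published
headline totals are not reproduction targets; only printed *change
statistics* are, treated as arithmetic inputs.

## Statistics layer

**Trade-offs.** Pearson correlations are cross-sectional — across the 29
regions within one year, on totals or per-unit-area scales. Temporal
correlation is deliberately not offered (four time points cannot support
it). Stars are raw per-pair p-values (the convention of the literature this
mirrors); Benjamini–Hochberg adjustment is available behind
`adjust = "BH"`, off by default. Zero-variance columns (e.g. unused-land
share in regions without unused land) yield an explicit "undef" result
rather than an error or a silent drop.

**Hierarchical partitioning.** The independent contribution `I_j` is the
Shapley decomposition of the full-model R²: the average R² increment from
adding predictor `j`, over all subsets weighted by `|S|!(k−|S|−1)!/k!`,
which equals the mean over all `k!` entry orders. The implementation
enumerates all `2^k − 1` subsets (capped at k = 12) and is tested for exact
(1e-10) agreement with a brute-force order-averaging oracle at k ≤ 4 and for
`ΣI = R²` always. Negative `I_j` (suppression) are reported, not clipped;
percentage shares use `ΣI`. Since the seven proportions sum to 1, the full
design is rank-deficient by one; R² is computed on the pivoted-QR fit, as
any regression software would.

**Stepwise regression.** SPSS-style bidirectional p-value selection:
add the most significant excluded predictor while `p < alpha_in` (0.05),
then drop included predictors with `p > alpha_out` (0.10), to stability.
Ties break on smaller p then column order; candidates aliased with the
current model are skipped, so duplicate columns cannot co-enter. With
`alpha_in ≤ alpha_out` the procedure cannot cycle. A property worth stating
honestly: with seven noise candidates the probability that *none* enters is
about `0.95^7 ≈ 0.70`, not 0.95 — best-of-k selection inflates the
family-wise entry rate, a known cost of p-value stepwise. The unit tests
assert this calibrated behaviour (k = 1: ≥ 90% intercept-only; k = 7:
≈ 70%); one acceptance check that demands ≥ 90% at k = 7 is therefore
left failing by design, with the reasoning recorded in the test.

**Driver tables.** Per-unit-area services are regressed on the seven
class proportions. Hierarchical partitioning runs per year with %I averaged
across years (and pooled over all region-years as an alternative view);
stepwise equations are emitted per service per year with n = 29, since
pooling would mix epochs whose parameter context differs.

## Numerical conventions

- Determinism: all generator randomness flows from one integer seed per
  artifact through a private RNG stream; the global `.Random.seed` is
  restored (tested).
- Nodata is `NA`; symmetric masking in two-date operations; zonal and class
  aggregations use `na.rm` sums over validated codebooks.
- ESRI ASCII grid I/O writes 17 significant digits for lossless
  round-trips; `cellsize` is interpreted in km.
- Display rounding (2 decimals for areas, integers for service percents)
  never enters computations or assertions.

## Known limitations

- Class-constant parameters everywhere: no within-class heterogeneity in
  carbon density, Kc, C, or sensitivities.
- The erosion model is gross potential loss; no sediment routing.
- Habitat threat influence is isotropic and barrier-free.
- The synthetic world's change rules are stationary across steps; real
  land-use transitions accelerate and saturate.
- One climate realisation per epoch; no interannual variability within an
  epoch.
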