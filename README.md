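# ecoserv

Raster-based ecosystem-service modelling and land-use driver attribution for
categorical land-use landscapes, with a fully synthetic, seeded data
generator so the complete analysis runs — and is testable — without any
external rasters.

`ecoserv` is aimed at landscape ecologists and regional planners who want to
quantify how land-use composition controls multiple ecosystem services
across administrative regions and decadal time steps. It implements five
per-cell service models of the kind popularised by the InVEST toolkit and
the equivalent-factor valuation literature, the land-use change accounting
that connects them to transition dynamics, and the statistics layer
(trade-off correlations, hierarchical partitioning, stepwise regression)
used to attribute service variation to land-use proportions.

## The models

All models operate on a seven-class land-use raster (forest, grassland,
water, urban/rural, unused, paddy, dry cropland) with per-class parameter
tables shipped as plain-CSV fixtures.

- **Carbon sequestration** — per-class pool bookkeeping,
  `C_tot = C_above + C_below + C_soil + C_dead` (t/hm²), mapped over the
  raster; totals in 10⁸ t.
- **Annual water yield** — Budyko–Fu partitioning per cell:
  `Y = P − AET` with `AET/P = 1 + PET/P − (1 + (PET/P)^ω)^{1/ω}`,
  `ω = Z·AWC/P + 1.25`, `PET = Kc·ET₀`, `AWC = PAWC·root_depth`;
  volumes in 10⁸ m³.
- **Potential soil erosion** — USLE, `A = R·K·LS·C·P_c`, with monthly
  rainfall erosivity `R = 1.2157 Σᵢ 10^{1.5·lg(Pᵢ²/P) − 0.0818}`;
  totals in 10⁴ t.
- **Habitat quality** — distance-decayed threat influence (linear or
  exponential, nearest-source by default), degradation
  `D = Σ_r (w_r/Σw)·ī_r·S_{jr}`, quality
  `Q = H_j·[1 − D^z/(D^z + k^z)]` with `k` half the realised maximum
  degradation.
- **Food-material supply** — equivalent-factor valuation,
  `value = area(hm²) × equivalent × E₀` with `E₀ = 1505.8` Yuan/hm²;
  totals in 10⁸ Yuan.

On top sit land-use transfer matrices with change statistics, a
region × year service panel, Pearson trade-off/synergy matrices with
significance stars, hierarchical partitioning of R² (exact Shapley
decomposition over all predictor subsets), and SPSS-style bidirectional
p-value stepwise regression.

The synthetic-landscape generator emulates a large agricultural river basin
in eastern China's north–south climate transition: ~49% dry cropland,
spatially autocorrelated patches, 29 contiguous regions, a 992.9 mm mean
annual precipitation rising southwards, and decadal change dominated by
urban expansion onto cropland. Every artifact is a pure function of its
spec and one integer seed.

## Worked example

```r
library(ecoserv)
res <- run_pipeline(pipeline_config(spec = landscape_spec(seed = 1)), quiet = TRUE)
res
#> <pipeline_result> 4 epochs (1990, 2000, 2010, 2020), 29 regions, 200x200 grid
#> domain totals by year:
#>  year carbon water_yield erosion food_material habitat
#>  1990  4.775       148.9    3896         64.44 0.10742
#>  2000  4.738       152.7    4044         63.57 0.10396
#>  2010  4.703       156.3    4185         62.70 0.10152
#>  2020  4.669       159.7    4323         61.84 0.09565
```

Carbon (10⁸ t), habitat quality and food-material supply (10⁸ Yuan) decline
as urban land expands onto cropland, while water yield (10⁸ m³) and
potential erosion (10⁴ t) rise with the wetter epochs — the qualitative
signature the generator's change rules plant.

```r
service_correlation_matrix(res$panel, 2020, per_unit = TRUE)
#> <correlation_matrix> year 2020, per_unit scale, n = 29 regions
#>               carbon  habitat  water_yield erosion food_material
#> carbon        1       0.97***  -0.50**     -0.35ns -0.54**
#> habitat       0.97*** 1        -0.41*      -0.24ns -0.70***
#> ...
```

The strong carbon–habitat synergy (r = 0.97) arises because both services
load on the same land-use classes (forest up, built-up land down) — exactly
the mechanism driver attribution then quantifies:

```r
round(res$drivers$contributions, 1)   # average %I across the four years
#>           carbon habitat water_yield erosion food_material
#> forest      45.0    41.4        33.3    21.0          19.3
#> grassland    8.5    12.3         6.8     7.5          13.2
#> ...
```

Forest proportion independently explains ~45% of the regional variation in
carbon per unit area, with dry and urban land next — the hierarchical
partitioning view of "which land use controls which service".

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline on the default 200×200, four-epoch synthetic
landscape with all randomness derived from `--seed`, prints the domain
service totals and the driver-contribution table, and writes the JSON
report to `--out`.
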