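# pollugrid

Grid-based tracking of industrial pollution sources: constant-quality
emission indices on an equal-area 100 km raster, spatial-clustering
diagnostics, and the regressions that link emissions to nearby
cancer-village locations and to policy regime shifts.

## What it does

Environmental monitoring stations measure pollution where the sensors
are, after wind and rivers have moved it. Firm-level self-reported
emission records measure pollution *at the source*. pollugrid implements
the full pipeline for turning a firm-year pollutant panel (wastewater,
COD, SO2, with firm covariates and WGS84 coordinates) into
source-tracking analyses:

* **Gridding** — an equal-area projection (spherical Albers conic),
  100 km × 100 km cells with half-open membership, per-cell-year
  aggregation (firm-free cell-years are missing, not zero).
* **Interpolation** — the Modified Shepard locally weighted scheme:
  local weighted-least-squares quadratics `Q_k` blended with compactly
  supported weights `W_k(q) = ((R_k − d_k)₊/(R_k d_k))²`, exact at the
  data cells, continuous, quadratic-reproducing.
* **Indices** — `Index_ij = (r_ij − min r) / (max r − min r)` with the
  min/max pooled over all cells *and* years per pollutant, so indices are
  comparable across space and time; regional mean series and percent
  changes.
* **Spatial autocorrelation** — global Moran's I
  `I = (n/S0) · Σᵢⱼ wᵢⱼ zᵢ zⱼ / Σᵢ zᵢ²` and Anselin's Local Moran's I
  `Iᵢ = (zᵢ/m₂) Σⱼ wᵢⱼ zⱼ` with conditional-permutation pseudo p-values
  and HH/LL/HL/LH cluster labels (LISA maps).
* **Health link** — firms assigned to cancer-village buffer rings
  (≤ 40 km treated, 40–80 km control, beyond excluded; nearest village,
  haversine), Welch balance tests, and OLS of log emissions on the
  buffer dummy and its Five-Year-Plan interactions with industry + year
  fixed effects.
* **Regime shifts** — grid-panel regressions
  `Index_it = α + β₁ year×east + β₂ year + X Γ + λ_cell + ε` fitted
  separately to the 10th (2001–2005) and 11th (2006–2010) FYP windows
  with CR1 cell-clustered errors, plus a contrast that flags trend sign
  flips between windows.
* **Synthetic data** — a seeded generator (clustered firm locations,
  log-linear emissions with a piecewise trend, villages at top-emitting
  clusters) that records its ground truth, so every stage has a
  recovery test.

Everything is plain base R; rasters are written as georeferenced ESRI
ASCII grids plus PNG previews, tables as CSV and journal-style text.

## Worked example

```r
library(pollugrid)

cfg <- sim_config(seed = 42)        # 8 clusters, 1998-2012, break at 2006
sim <- simulate_firm_panel(cfg)
sim
#> firm_panel_sim: 5445 firm-years (363 firms x 15 years), 3 villages

buf <- assign_buffers(sim$panel, sim$truth$villages)   # 40/80 km rings
panel <- merge(sim$panel, buf[, c("firm_id", "buffer")], by = "firm_id")
fit <- fit_firm_regression(panel, "cod", covariates = c("lnsize", "lnage", "roa"))
fit
#> Fixed-effects OLS (plain standard errors), N = 2160, R-squared = 0.736
#> Absorbed fixed effects: factor(industry), factor(year)
#>         term  estimate std_error t_value  p_value stars
#>  (Intercept)  4.974353   0.09823 50.6375 0.000000   ***
#>       buffer  0.158034   0.05092  3.1035 0.001938   ***
#>       lnsize  0.818910   0.01247 65.6903 0.000000   ***
#>        lnage -0.005718   0.02285 -0.2503 0.802403
#>          roa  0.175193   0.15480  1.1317 0.257885
#>   buffer:k10  0.060839   0.06266  0.9710 0.331657
#>   buffer:k11  0.020644   0.05922  0.3486 0.727435
```

N = 2160 is the estimation sample inside the 80 km ring system (firms
beyond the outer ring are excluded). The `buffer` coefficient estimates
the log-emission premium of firms within 40 km of a cancer village —
here 0.158 against a generating value of 0.2, with the truth well inside
the 95% interval; `lnsize` recovers the generating size elasticity 0.8.
The FYP interactions are near zero because the generator's premium is
period-constant.

The whole pipeline — synthetic panel → grid → Shepard surfaces → indices
→ Moran/LISA → both regression stages → hashed artifact manifest — runs
from one config:

```r
res <- run_pipeline(default_run_config(seed = 7, outdir = "out"))
res$index_changes      # percent change of each pollutant's mean index
```

A thin command-line wrapper lives at `inst/cli/pollugrid.R`
(`Rscript pollugrid.R all --config cfg.yaml --seed 7 --outdir out`).

## Layout

* `R/` — generator, geodesy/gridding, Shepard interpolation, indices,
  Moran/LISA, regressions, pipeline, raster IO
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (brute-force scans, closed forms, demeaning)
* `vignettes/pollugrid-methods.Rmd` — the methods vignette: model
  details, parameter defaults and rationale, what the synthetic system
  does and does not emulate, numerical edge cases, limitations
* `inst/cli/pollugrid.R` — command-line wrapper
* `inst/extdata/province_regions.csv` — editable province → region map
  for real-data runs
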