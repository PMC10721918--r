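---
title: "Methods: grid-based emission indices, spatial clustering and regime shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based emission indices, spatial clustering and regime shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollugrid)
```

# The analysis pollugrid implements

pollugrid turns a firm-year panel of self-reported pollutant quantities
(wastewater in tons/yr, COD and SO2 in kg/yr, with firm covariates and
WGS84 coordinates) into four linked products:

1. **Constant-quality emission indices** on an equal-area 100 km raster,
   built by aggregating firm emissions per cell, interpolating the cell
   surface with the Modified Shepard locally weighted scheme, and min-max
   normalising the interpolated levels.
2. **Spatial clustering diagnostics**: global Moran's I and Anselin's
   Local Moran's I (LISA) with permutation inference on the index
   surfaces.
3. **A health-proximity regression**: firm-level log emissions on
   cancer-village buffer rings (inner 40 km disk vs 40-80 km annulus)
   with industry and year fixed effects.
4. **Regime-shift regressions**: grid-panel index trends fitted
   separately to the 10th (2001-2005) and 11th (2006-2010) Five-Year-Plan
   windows, with cell fixed effects and cluster-robust errors, and a
   contrast that flags trend sign flips across the windows.

Because the real firm-level pollution database this kind of analysis runs
on is confidential, the package ships a synthetic-data generator with
recorded ground truth; every stage has a parameter-recovery or oracle
test against it.

# Gridding and geodesy

Firms are projected to a planar system before gridding. For real
longitude/latitude data the package provides a spherical **Albers
equal-area conic** projection (`albers_projection()`, standard parallels
25N/47N, central meridian 105E), the standard equal-area choice for a
China-wide raster: equal-area is what makes "100 km x 100 km" cells
comparable units. Synthetic panels live on an abstract plane embedded in
WGS84 by an exactly invertible equirectangular map (`plane_projection()`)
so the geodesic code paths are still exercised.

Cells use a **half-open membership convention** `[x_left, x_right) x
[y_bottom, y_top)`: a point on an interior edge belongs to exactly one
cell, so aggregation is a partition and grand totals are conserved
exactly. Firms outside the grid extent are excluded and reported, not
silently dropped.

A cell-year with no reporting firms is recorded as **missing, not zero**
(default `empty = "missing"`): absence of firms is not evidence of zero
emission, and zeros would bias the interpolated surface downward. A
zero-fill mode exists behind a flag for sensitivity analysis, since
either convention is defensible for reporting data.

Distances to villages use the haversine formula on a sphere of radius
6371.0088 km (the IUGG mean radius); at the 40-80 km scales of the buffer
analysis the spherical error is negligible.

# Modified Shepard interpolation

The cell surface for each pollutant-year is fitted with the Modified
Shepard scheme (Franke-Nielson construction with Renka-style weights):

* For each data node `k` (a non-missing cell centroid), a local quadratic
  `Q_k` is fitted by weighted least squares to the `nq` nearest other
  nodes, with the constant term pinned to the node's own value so `Q_k`
  interpolates it exactly. Fit weights `((Rq - d)/(Rq d))^2` vanish at the
  neighbourhood radius `Rq` (distance to the `nq`-th neighbour).
* The surface blends nodal functions with compactly supported weights
  `W_k(q) = ((Rw_k - d_k)_+/(Rw_k d_k))^2`, `Rw_k` the radius of node k's
  `nw`-neighbourhood: `F(q) = sum W_k Q_k(q) / sum W_k`.

Properties that the tests verify: exactness at nodes (the weight diverges
there), continuity, reproduction of any bivariate quadratic (quadratic
data lie in the span of every local fit, and a convex blend of exact
quadratics is exact), and reproduction of constants everywhere
(partition of unity).

**Defaults `nq = 13`, `nw = 19`** are the canonical neighbourhood sizes
for this scheme's reference implementations; both are exposed as
configuration because reasonable alternatives exist and the original
analyses that popularised this pipeline do not publish their settings.
Numerical edge cases are handled explicitly: fewer than 5 usable
neighbours degrade the local fit to linear, then constant;
rank-deficient local designs degrade the same way; coincident nodes with
equal values are merged and with conflicting values rejected; queries
outside every node's radius return the nearest node's value; tiny node
sets with unbounded radii fall back to plain inverse-distance-squared
weights. Negative interpolated levels are clamped to zero before
normalisation because emission levels are physical quantities.

# Index normalisation

`Index = (r - min)/(max - min)` with the min and max **pooled over all
cells and all years** per pollutant. The pooling choice matters: pooling
over space only would re-anchor the scale every year and make the time
series meaningless; pooling over both makes indices comparable across
space and time, which is what the regional time series and the
regime regressions require. A per-cell-over-time mode is available
behind a flag. A constant field yields all-zero indices with a warning
rather than dividing by zero.

One consequence worth knowing: with heavy-tailed emissions (lognormal
noise on an exponential scale) the pooled maximum is driven by the single
largest cell-year, so the mean index is small and its percent changes
between two years can be volatile across seeds. That is a property of
min-max indices, not a bug; the demo pipeline's printed percent changes
should be read with that in mind.

# Spatial autocorrelation

Weights are **queen contiguity, row-standardised** by default (the common
raster-LISA choice; rook and binary variants by flag), built on the cell
lattice with islands flagged. Global Moran's I uses the textbook
cross-product form with expectation `-1/(n-1)`; inference is by random
permutation of the values (999 draws by default, seeded), one-sided in
the direction of the observed departure, with the standard
`(1 + extreme)/(n_perm + 1)` pseudo p-value. Local Moran's I uses
conditional permutation (cell i's value held fixed, neighbours drawn
from the rest), quadrant labels HH/LL/HL/LH from the signs of the
deviation and its spatial lag, and cluster labels thresholded at
`alpha = 0.05` by default. Ties (a deviation or lag exactly zero) are
assigned to the "high" side; they have probability zero for continuous
data. The implementation stores weights in triplet form so permutation
loops stay vectorised.

# The two regression stages

**Firm level.** OLS of log pollutant on the buffer dummy, buffer x FYP
interactions (`k10`: 2001-2005, `k11`: 2006 on), firm and city
covariates, and industry + year dummy sets. Standard errors are plain by
default, matching the convention of the published tables this layout
mirrors; CR1 clustering is available. Zero pollutant values are handled
by `log(1+P)` by default with a strict-log mode that drops them — the
strict mode is what makes zero-noise recovery exact, while at realistic
emission scales (log levels around 5-10) the two differ negligibly.
Covariate presets: `"table1"` (includes export intensity) and
`"equation"` (includes unemployment); the two published lists disagree,
so both ship and neither is claimed canonical. Collinear covariates are
dropped and reported; a collinear *core* term (buffer or its
interactions) is an error, because the design then cannot answer the
question asked. Note the interactions are only identified when the panel
contains years outside both FYP windows; within 2001-2010 alone,
`buffer = buffer:k10 + buffer:k11` exactly.

**Grid level.** For each FYP window, OLS of the index on the centred year
(`year - window start`; centring moves only the intercept), optionally
`year x east`, and four province controls (gdppc, secondary, tertiary,
urbanrate), absorbing cell fixed effects via the dummy set. The `east`
main effect is constant within cells and thus absorbed. Standard errors
are **CR1 cluster-robust at the cell**, `G/(G-1) * (N-1)/(N-K)` times the
cluster-score sandwich — the finite-sample convention common in applied
panel work. The province-level join key for the controls is configurable
(the source analyses are ambiguous between province and prefecture
aggregation). `regime_contrast()` reports sign and significance of the
trend and interaction per window and flags a regime shift when the trend
flips sign with both windows significant at `alpha = 0.1` (the loosest
star of the published tables).

The tests verify both estimators against an independent iterated
within-demeaning (alternating projections) oracle to 1e-8 on all slopes,
and the CR1 covariance against a hand-rolled per-cluster loop to 1e-10.

# The synthetic study system

`simulate_firm_panel()` emulates the features of the real data that the
pipeline's behaviour depends on:

* **Matern-style clustered locations**: uniform parent centres, Poisson
  firm counts (mean 40/cluster, 8 clusters), Gaussian offsets with
  `cluster_sd_km = 30`. The 30 km spread was chosen so that firm mass
  falls on both sides of the 40 km village ring, giving both treated and
  control firms; it is also a plausible scale for an industrial
  agglomeration.
* **Log-linear emissions**: `ln P = b0_j + 0.8 lnsize + 0.2 buffer +
  trend + eps`, `eps ~ N(0, 0.5)`. The piecewise-linear trend rises
  +0.05/yr to 2006 and falls -0.08/yr after (so the trajectory peaks at
  the break and ends below its start), with East differentials +0.02/-0.01.
* **Villages at the top-emitting clusters**, jittered by half the cluster
  spread. Ranking uses the deterministic no-noise emission mass
  `sum(exp(beta_size * lnsize))`, which is computable before emissions
  are drawn — this is what breaks the circularity between "villages sit
  near high emissions" and "emissions are higher near villages", and it
  makes `simulate_cancer_villages()` reproduce the recorded ground-truth
  villages exactly.
* **Province covariates** follow linear province trends with noise; GDP
  shares are scaled to sum below 100 and rates clipped to [0, 100].

What it deliberately does **not** emulate: China's actual geography and
administrative shapes, the real database's marginal distributions,
measurement error or strategic misreporting in self-reported emissions,
firm entry/exit, and any cluster-level emission intercept. The last point
is a real limitation: in the generator, proximity to a village is
associated with emissions only through the built-in premium, whereas in
real data villages may sit near clusters that are dirty for unmodelled
reasons. Passing recovery tests therefore show the estimators are
correct under the stated model, not that the observational design is
confounding-free — the source analyses themselves disclaim causal
interpretation.

`simulate_grid_panel()` generates the grid-regression panel directly
(cell fixed effects N(0, 0.05), iid or AR(1) within-cell errors, known
trend coefficients). Its province covariates fluctuate around their
trends with sd 1.0 by default; with near-deterministic covariate trends
the four controls can almost reproduce the year regressor after
demeaning, leaving the trend barely identified — a multicollinearity
property of the design, not of the estimator, and the default keeps the
trend identified while still giving the controls realistic trending
behaviour.

All generators are seeded and byte-reproducible; the same config and
seed give identical output.

# Problem sizes and runtime choices

The shipped tests and the acceptance script use: 50 random node sets
(20-60 nodes) for interpolation exactness; an 8x8 raster for the Moran
oracle (100 fields); 20 replicates of ~30,000 firm-years for
buffer-premium coverage; 20 replicates of 400 cells x 5 years per window
for regime coverage; and a demo pipeline of ~3,000 firm-years on a 20x20
grid with 999 permutations, run twice to verify byte-identical
artifacts. These sizes give stable Monte-Carlo summaries (e.g. 80 CI
checks for regime coverage) while keeping a full run in the low minutes
on a single CPU.

# Outputs

Every pipeline stage writes plain-text artifacts: CSV tables, GeoJSON
village points, georeferenced ESRI ASCII grids (`.asc`) for index
layers, PNG previews (monotone ramp for indices, the fixed five-colour
HH/LL/HL/LH/not-significant palette for LISA maps), journal-style text
regression tables with the usual 0.1/0.05/0.01 star convention, and a
`manifest.csv` of MD5 hashes. Identical config and seed reproduce
identical hashes, which is the package's end-to-end determinism
contract.
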