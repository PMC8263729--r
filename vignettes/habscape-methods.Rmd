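---
title: "habscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{habscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habscape)
```

`habscape` couples a raster habitat-quality model with land-use transition
statistics, basin-level urbanization indicators, geographically weighted
regression and self-organizing-map zoning. This vignette documents the
models, every tunable that matters, the numerical choices, and what the
synthetic generators do and do not emulate.

## The habitat quality model

Each cell `x` carries a land-use class `j`. Habitat degradation aggregates
exposure to a set of threat sources `r`:

$$D_{xj} = \sum_r \frac{w_r}{\sum_r w_r}\; \mathrm{dens}_r(x)\; \beta_x\; S_{jr}$$

* `dens_r(x)` is the distance-decayed density of threat `r` around `x`.
  Per source cell `y` the interference at distance `d_xy` (straight-line,
  centre-to-centre, projected metres) is either linear,
  $1 - d_{xy}/d_{r\max}$, or exponential, $\exp(-2.99\, d_{xy}/d_{r\max})$,
  and exactly zero beyond the maximum threat distance $d_{r\max}$
  (kernel truncation). Note $\exp(-2.99) \approx 0.0503$: the exponential
  law does not reach zero at $d_{r\max}$; the truncation makes it.
* `w_r` are threat weights, normalized to sum to one inside the formula, so
  `D` is invariant to rescaling all weights — only relative weights matter.
* `S_{jr}` in [0, 1] is the sensitivity of habitat class `j` to threat `r`
  and `β_x` in [0, 1] is accessibility.

Quality is the half-saturation transform of degradation,

$$Q_{xj} = H_j\left(1 - \frac{D^2}{D^2 + k^2}\right),$$

with `H_j` the intrinsic suitability of class `j`, so `Q = H` for pristine
cells and `Q = H/2` at `D = k`. Quality is graded into five levels at 0.2
steps with half-open intervals [0, .2), [.2, .4), [.4, .6), [.6, .8),
[.8, 1]: a cell at exactly 0.2 is grade II, and 1.0 closes grade V.

### Density normalization (a deliberate reading)

The raw decayed sum $\sum_y r_y\, i_{rxy}$ is unbounded: it grows with the
number of source cells in range, and no choice of weights keeps the
resulting `D` inside [0, 1] on arbitrary rasters. We therefore normalize
each threat's decayed sum by the decayed sum the kernel would attain if
*every* in-bounds cell in range were a source. Under this reading
`dens_r ∈ [0, 1]` (1 = saturated threat neighbourhood, 0 = none), and the
stated range `D ∈ [0, 1]` holds for any landscape. The normalizer uses only
in-bounds cells — no phantom padding — so an all-threat map yields density 1
at the edges too. `threat_density(..., normalize = FALSE)` returns the raw
sums for users who want the unnormalized variant.

A consequence worth knowing: threat cells score their own kernel
(self-distance 0 contributes decay 1), so a cropland cell is degraded by the
cropland threat around and including itself, with its own sensitivity row.

### Default parameterization

`threat_table()` ships six threats (maximum distance in km, weight, decay
law): cropland (5, 0.5, exponential), city/town (9, 1.0, exponential), rural
settlements (6, 0.6, exponential), other construction land (2, 1.0,
exponential), unused land (1, 0.4, linear), sea reclamation (2, 0.3,
linear). `sensitivity_table()` carries the eleven habitat classes with their
suitability `H` and per-threat sensitivities; the three construction
subtypes are intentionally absent and default to `H = 0`, `S = 0`
(non-habitat), silently — a genuinely unknown code triggers a warning
instead. The three construction subtypes are treated as disjoint source
sets.

Two model inputs are exposed because no authoritative value exists:

* **Half-saturation `k`** (default 0.5, dimensionless on the degradation
  scale). This is the conventional default of threat-based habitat models
  and places the quality midpoint at half the observable degradation range.
* **Accessibility `β`** (default 1 everywhere). The model accepts an
  accessibility raster, but absent protected-area data a neutral multiplier
  is the only defensible default.

## Numerical implementation

Threat densities are convolutions of the 0/1 source mask with the truncated
decay kernel. They are evaluated by zero-padded FFT (and the normalizer as
the convolution of the validity mask with the same kernel), which is exact
up to floating-point roundoff; the test suite bounds the deviation from an
independent brute-force pairwise-distance evaluation below 1e-10 on hundreds
of random landscapes (observed ~1e-16). Densities are clamped to [0, 1]
after the division to remove roundoff excursions. Kernels are clipped to the
grid extent: offsets that can never land in-bounds are dropped before the
FFT, which only changes speed, not values.

Degradation is monotone: converting a cell of a non-threat class into a
threat class can only raise `D` and lower `Q` at every *other* cell. At the
converted cell itself the property need not hold — its own sensitivity row
and suitability change with its class (e.g. water is sensitive to cropland
but cropland is not sensitive to itself), so `D` there may drop and `Q` may
rise. The monotonicity tests therefore assert the property over unchanged
cells, which is the form that is actually true of the model.

## Transition statistics

Transition matrices cross-tabulate co-registered cells; cells that are
nodata at either epoch are excluded from all statistics. For a conversion
set (from-classes → to-classes) with `n` cells:

* `HQCI = mean(Q_t2 − Q_t1)` over the converted cells (t2 − t1: negative =
  loss),
* `S = n ×` cell area (km²),
* `CI = HQCI × S`, identically the summed per-cell change times cell area.

HQCI is a *mean per-cell* index and CI a *total*: that pairing is the only
one under which published transition tables are internally consistent
(CI / S reproduces the printed HQCI in all six reference rows bundled as
`transition_reference()`). An absent transition (`n = 0`) reports `NA`, not
zero — "no conversion" and "conversion with zero net effect" are different
findings. Report columns are rounded to 2 decimals; the unrounded path
(`digits = NULL`) satisfies `CI = HQCI × S` to 1e-9 relative and is used for
the decomposition identity (summed donor CIs equal the total quality change
over all newly-construction cells).

Grade bookkeeping reports per-epoch grade shares (%, summing to 100) and
per-period grade area changes (km²); consecutive period deltas telescope
exactly to the full-period delta before rounding.

## Basin indicators and regression

Basins aggregate the grid: per-basin mean quality, mean NTL, mean POP, and
the land urbanization rate (construction share of basin area). Means rather
than sums are used for NTL/POP so indicators are scale-free with respect to
basin area; users wanting totals can multiply by area. Standardization is
min–max by default — the four-indicator SUM is then interpretable on a
common 0–4 scale — with z-scores available (constant columns are rejected
there, mapped to 0 under min–max).

OLS and GWR are implemented from scratch (QR for the global fit; per-unit
weighted least squares for GWR). Model comparison uses the small-sample
corrected AIC in its hat-trace form for *both* models (trace = p for OLS),
so AICc values are directly comparable; `sigma = sqrt(RSS / (n − trace))`
likewise. GWR kernels: Gaussian (default; every observation keeps positive
weight, which protects small-`n` basin sets from rank-deficient local fits),
adaptive bisquare (k-nearest) as an option, and a uniform kernel that
reproduces OLS exactly — used as an internal consistency check. Bandwidth is
selected by deterministic golden-section search on AICc over 1%–200% of the
coordinate extent. Regressions are univariate by default (one fit per
indicator, matching per-indicator coefficient surfaces); multivariate
designs are accepted by the same functions. GWR is *preferred* only when
both AICc and sigma are lower; numerically indistinguishable fits are
flagged ambiguous rather than ranked.

## SOFM zoning

A classic online Kohonen map: best-matching unit by Euclidean distance,
Gaussian neighbourhood on the neuron grid, exponentially decaying learning
rate (0.5 → 0.01) and radius (1 → 0.1) over 500 epochs by default, weights
initialized from seeded random data rows. The map is 2 × 2 by default so the
four neurons *are* the four zones; larger maps work, with however many
non-empty neurons result (fewer than the map size is flagged as degenerate).
Zones are relabelled A–D by descending mean member SUM, so the lettering is
data-driven and invariant to neuron indexing: A is always the
highest-joint-development group. Training is a pure function of the seed;
the quantization error trace is stored for inspection and settles (no upward
trend beyond the jitter left by the floor learning rate) on well-separated
data.

## The synthetic generators

The generators produce data with the statistical structure the analysis
assumes, emulating a 30 m categorical land-use product, decadal urban
growth, light/population covariates and a basin partition:

* `generate_landscape()` plants `n_urban_seeds` compact connected urban
  clusters (nearest-cells-to-seed disks, which are provably 4-connected) and
  bands the remaining area into the natural classes along a Gaussian-
  smoothed random field, so class proportions match the requested mix up to
  integer rounding while classes stay spatially clustered. The smoothing
  radius (default sigma 6 cells) is a free parameter of the generator, not
  an inference about any real product.
* `grow_urban()` converts `round(growth_rate × non-urban cells)` per step
  with probability weight `exp(compactness × 3×3 urban fraction)`, drawn by
  exact weighted sampling without replacement (exponential-race keys). This
  reproduces compact, core-clinging expansion qualitatively; it is not a
  calibrated urban growth model.
* `generate_covariates()` makes NTL and POP affine in the kernel-smoothed
  built-up density plus seeded noise, clamped non-negative — positive
  correlation with urbanization is built in, which is the property the
  regression stage needs.
* `generate_basins()` grows a grid-geodesic Voronoi partition by
  multi-source BFS (guaranteeing 4-connected basins, which Euclidean
  nearest-seed labelling does not) and then merges sub-threshold basins
  smallest-first into the neighbour sharing the longest border (ties to the
  lowest label), default threshold 5 km².

What they do **not** emulate: hydrological (DEM/flow-accumulation) basin
delineation, sensor intercalibration or saturation artefacts in nighttime
lights, census-anchored population surfaces, mixed native resolutions
(covariates are generated at the land-use resolution; `resample_grid()`
provides block aggregation when coarser inputs are wanted), coastline
geometry, or any policy dynamics. Passing tests on synthetic data therefore
validates the *computations* — kernels, indices, estimators, clustering —
not the realism of any particular regional dataset.

All generator randomness flows through one explicit integer seed per
operation; every generator is a pure function of its arguments.

## Problem sizes and runtime choices

The test suite and the acceptance script exercise: 128 × 128 to 256 × 256
landscapes for the pipeline and proportion checks; 32 × 32 landscapes
(100 replicates) for the brute-force degradation oracle, whose pairwise
distance matrix grows with the fourth power of the grid edge; 400 units for
GWR recovery and SOFM planted-cluster runs; 200 perturbation trials on
16 × 16 grids for the monotonicity property. These sizes give stable
statistics in seconds; every stage scales to much larger grids (the FFT
convolution is `O(N log N)` in cell count), with GWR's dense `n × n`
distance matrix the first practical ceiling (fine to a few thousand basins).

## Known limitations

* Degradation's bounded range depends on the kernel normalization described
  above; with `normalize = FALSE` the raw sums are unbounded and the
  half-saturation `k` must be rescaled by the user.
* `D` and `Q` surfaces are only as good as the threat/sensitivity tables;
  the shipped defaults encode one published regional parameterization of a
  generic threat-based model.
* GWR inference is descriptive here: no standard errors or spatial
  autocorrelation diagnostics are computed.
* The SOM is an online (sample-by-sample) implementation; results depend on
  the seed by design, and the planted-cluster tests quantify, rather than
  eliminate, that variability.
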