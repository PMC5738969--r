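---
title: "Bottom-up population estimation: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up population estimation: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bupop)
library(dplyr)
```

## The problem

In settings where the last reliable census is a decade or more old,
population denominators for health planning (vaccination campaigns, survey
design, service delivery) are usually produced by projecting old census
counts forward at an assumed growth rate. Where growth is fast and uneven
that assumption fails badly. The *bottom-up* alternative implemented here
builds the denominator directly from two observable ingredients:

1. a **settlement layer** — a fine binary raster marking land covered by
   buildings, derived from satellite imagery; and
2. a **microcensus** — complete enumeration of residents in a sample of
   small zones (microcensus enumeration zones, MEZs) of a few hectares
   each, giving observed population densities per settled hectare.

Density observations are attached to a **residential-type layer**: block
polygons classified into six urban types (`A`–`F`), one rural type (`M`)
and a non-residential type (`Z`). Multiplying modelled density by mapped
settled area yields population estimates for any region, with no census
input at all.

`bupop` implements the full estimation chain, and — because the imagery
and survey data behind the original deployment are proprietary — a
synthetic-landscape generator that emulates their statistical structure so
every stage can be exercised and tested end to end.

## Density models

Residential density per settled hectare is the product of multiplicative
factors (building spacing, height, occupancy), so it is modelled as
log-normal. Two models are fitted:

* **Model 1** (control): all unstratified first-round (DS1) observations
  pooled, \(D \sim \mathrm{Lognormal}(\mu, \sigma^2)\) — the situation
  where a settlement map exists but no type classification.
* **Model 2**: one sub-model per residential type on the combined
  DS1 + DS2 observations,
  \(D_t \sim \mathrm{Lognormal}(\mu_t, \sigma_t^2)\) for
  \(t \in \{A,\dots,F,M\}\), and \(D_Z = 0\).

Estimation is moment matching on the log scale (the Gaussian MLE with the
\(n-1\) variance denominator), with the standard Gaussian standard errors
\(\mathrm{se}(\hat\mu) = \hat\sigma/\sqrt{n}\) and
\(\mathrm{se}(\hat\sigma) = \hat\sigma/\sqrt{2(n-1)}\). Only the
distributional form is prescribed by the method; the estimator and its
standard errors are this package's (conventional) choices, pinned by
tests. A type observed fewer than twice gets no model and is flagged so
the caller must supply a fallback rather than receive a silent guess.
Type-level skewness anomalies (one type in the original data is slightly
left-skewed) are ignored: the log-normal is fitted regardless, which keeps
the model family uniform.

## Gridded estimates

The point-estimate raster is the product of three aligned fine
(0.25 arc-second) rasters — type mean density (persons/ha), binary
settlement, and cell area in hectares — summed into 3 arc-second cells
(144 fine cells each) and rounded half-away-from-zero to integers.
Cell areas use the exact spherical band formula
\(R^2\,\Delta\lambda\,(\sin\varphi_2-\sin\varphi_1)\) with
\(R = 6{,}371{,}007.181\) m, so nested sub-cells sum *exactly* to their
parent cell and aggregation is conservative before rounding (tests assert
both, plus the ≤ 0.5-per-cell rounding bound).

The per-type "mean estimate" painted onto blocks is the **arithmetic
sample mean** of observed densities — the quantity the published summary
tables report — not the analytic log-normal mean
\(e^{\mu + \sigma^2/2}\). The analytic alternative is available via
`make_density_raster(..., estimate = "lognormal")`. The two differ when
\(\hat\sigma\) is noisy; the arithmetic mean is the more conservative,
table-consistent default. Cell membership is by cell centre, with ties on
shared block edges resolved to the lexicographically lowest type code.

## Prediction intervals by Monte Carlo convolution

For uncertainty, each residential type gets a **reference area**
\(\phi_t\): the mean settled area of its surveyed zones. Densities are
re-expressed as residents per \(\phi_t\), which on the log scale shifts
only the location: \(\mu_{t\phi} = \mu_t + \ln\phi_t\),
\(\sigma_{t\phi} = \sigma_t\).

A region of interest is decomposed into a **portion table**: per type, its
settled area \(a_t\) and area factor \(k_t = a_t/\phi_t\). One realization
of the region's count sums, over types, \(\lceil k_t\rceil\) independent
draws from the reference-scale log-normal, the last draw scaled by the
fractional part of \(k_t\) (a full draw when \(k_t\) is integer; a single
draw scaled by \(k_t\) when \(k_t < 1\)). With 10,000 realizations the
empirical 0.05/0.95 quantiles give the 90% prediction interval; quantiles
use linear interpolation between order statistics (type 7) so results are
bit-reproducible under a fixed seed. Draws are independent across types
and replicates — the i.i.d. assumption of the method; spatial
autocorrelation between neighbouring zones is a known, deliberate
omission.

### Parameter uncertainty: per-draw vs per-realization

Estimation error in \((\hat\mu_t, \hat\sigma_t)\) can be propagated by
perturbing the parameters with their standard errors. Two variants exist:

* `perturb = "draw"` redraws \(\mu^* \sim N(\hat\mu, \mathrm{se}^2)\)
  independently for *every draw*. For large \(k\) these perturbations
  average out across the \(k\) draws, so the common (region-wide)
  component of estimation error is under-propagated.
* `perturb = "realization"` draws one \((\mu^*, \sigma^*)\) per type per
  realization, holding the parameter error fixed across the region — the
  variant that actually matches how estimation error enters a zonal
  prediction, and the one used in the coverage calibration suite, where
  90% intervals cover generated ward truths for 86–94% of wards.

Both are provided; `"draw"` remains the default because it follows the
per-draw description of the procedure, and the calibration analysis above
is documented here precisely so users know when to prefer
`"realization"`.

## Subpopulations and validation

Under-5 counts are the simulated total-population realizations multiplied
by the under-5 fraction of the (≈1 km) demographic grid cell nearest the
region centroid — a deliberate single-cell lookup, matching how such
fraction surfaces are used operationally; an area-weighted variant exists
behind a flag for sensitivity checks. Validation against reference counts
uses the zero-intercept regression
\(\hat\beta = \sum x_i y_i / \sum x_i^2\) with
\(R^2 = 1 - \mathrm{RSS}/\sum(y_i-\bar y)^2\); the \(R^2\) definition is
not standardized for through-origin fits, so this package documents and
tests its formula explicitly.

## The synthetic landscape: what it emulates, and what it does not

`generate_landscape()` produces the study conditions end to end:

* **Settlement**: random disks accreted on the fine grid until a target
  settled fraction (default 0.02 — in the semi-arid settings emulated,
  1–3% of land is settled) is reached, giving contiguous clumps rather
  than salt-and-pepper noise, with a ±15% accretion guard so the realized
  fraction stays well within ±20% of target.
* **Type mosaic**: blocks are cells of a jittered rectangular lattice
  (pitch drawn per row/column band, most blocks 1–20 ha) clipped to
  settlement, so they partition the settled extent exactly. Types are
  assigned longest-block-first to the largest remaining area quota of a
  target mix (default dominated by rural `M` at 0.76, with small urban
  shares and 5% `Z`), tracking the mix as closely as block granularity
  allows.
* **Truth**: each residential block draws one true density from its
  type's generating log-normal. Defaults are calibrated so arithmetic
  type means match the published survey means (e.g. ≈337 persons/ha for
  type B, 246 for M) with \(\sigma_t \in [0.3, 0.9]\); they live in
  `landscape_config()`, not in code.
* **Microcensus**: DS1 samples residential settled cells uniformly; DS2
  stratifies across urban types. Both honour the survey protocol's 500 m
  great-circle exclusion rule, which also keeps observations in distinct
  blocks (without it, repeated sampling of the same blocks visibly biases
  parameter recovery). MEZs are squares grown around the sample point,
  clipped to the containing block as real enumeration zones are, until
  the settled intersection reaches a target of 1–6 ha. Enumeration is
  per building (25–50 buildings where the population supports it), each
  count rounded to an integer, with a one-resident floor.

Passing tests on this landscape demonstrate that the estimation chain is
correct *under the model's own assumptions*: independent log-normal
densities, exact type maps, exact settlement. They do not demonstrate
robustness to classification error, settlement omission, within-block
density gradients, or spatial autocorrelation — all real phenomena the
original deployment discusses and this package deliberately does not
model.

## Numerical and design notes

* Grids are equal-angle, degree-based; there is no projected-CRS support.
  Cells are half-open intervals so adjacent cells never double-count.
* Rounding of population counts is half-away-from-zero.
* `pool_dataset_means()` is exact count weighting; it reproduces the
  published combined survey means from the printed per-round rows to the
  printed precision for every type except one, where the original table
  evidently pooled unrounded values (the discrepancy is one unit in the
  final printed digit).
* Compound annual growth of built-up area is
  \(100\,[(f_2/f_1)^{1/\text{years}} - 1]\); recomputing from rounded
  published fractions gives 2.03%/4.46% for the two epochs where 2.02%/
  4.37% were printed from unrounded inputs.
* Empty settled intersections are errors, not zero densities; zero-area
  regions yield empty portion tables and trivially zero populations;
  all-`Z` regions simulate to exactly zero.

## Problem sizes used in the test suite

Tests run on landscapes of 400×400 to 720×720 fine cells with 1–2
arc-second cells, microcensus samples of 25–80 zones, simulations of
1,000–20,000 realizations, and the coverage suite uses 500 synthetic
wards (10 seeds × 50 wards) at 1,000 realizations each — sizes chosen so
the whole suite completes in well under a minute while leaving Monte
Carlo error far smaller than the tolerances asserted.

## A worked example

```{r example, eval = FALSE}
cfg <- landscape_config(seed = 1)
ls0 <- generate_landscape(cfg)

ds1 <- generate_microcensus(ls0, "DS1", n_locations = 60, seed = 2)
ds2 <- generate_microcensus(ls0, "DS2", n_locations = 8, seed = 3)
obs <- dplyr::bind_rows(ds1, ds2)

models <- fit_model2(obs)
smry <- summarize_dataset(obs, label = "Combined")
phis <- setNames(smry$mean_sample_area_ha, smry$type)

ward <- c(8.45, 8.475, 11.95, 11.975)
pt <- build_portion_table(ward, ls0$blocks, ls0$settlement, phis,
                          roi_id = "ward-1")
sim <- simulate_roi(pt, models, n_realizations = 10000, seed = 4)
glance(sim)
autoplot(sim)
```
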