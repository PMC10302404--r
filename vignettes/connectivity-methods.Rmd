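---
title: "Classifying wetland hydrologic connectivity from raster landscapes"
author: "wetconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying wetland hydrologic connectivity from raster landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetconnect)
```

## The model

`wetconnect` assigns every wetland unit on a raster landscape to one of four
hydrologic connectivity classes, ordered from highest to lowest
connectivity: Riparian, NRShw (non-riparian shallow), NRMid (non-riparian
mid-depth) and NRDeep (non-riparian deep), plus an explicit Unclassified
category for units the evidence cannot place. The classification is
*structural*: it describes the pathways water would take given water
availability, not the observed frequency of flow. It deliberately excludes
travel-time factors such as flowpath length and slope — two wetlands with
flowpaths of equal length are distinguished by how quickly water would move
through those paths (soil permeability and drainage), not by how far it
must go.

The decision flow, applied per wetland unit:

1. If the unit's pour point lies within one pixel — Chebyshev distance ≤ 1,
   so ordinal and cardinal neighbors count equally — of a buffered-stream
   cell, the unit is **Riparian**. Soils are never consulted; a wetland in
   contact with the channel exchanges water bidirectionally regardless of
   its soils.
2. Otherwise the D8 flowpath from the pour point is traced downstream,
   crossing catchment boundaries freely, stopping just before the first
   buffered-stream cell. If the trace fails (leaves the grid, meets nodata
   flow directions, loops, or exhausts its step budget), the unit is
   **Unclassified**.
3. The minimum saturated hydraulic conductivity (Ksat, cm h⁻¹) over path
   cells is compared with the permeability threshold. Below it the flowpath
   is impermeable: **NRDeep**. The minimum is used because the least
   permeable segment limits flow through the whole path.
4. For permeable flowpaths, each path cell's NRCS drainage class (codes
   1–7) is grouped into *poorly drained* (somewhat poorly, poorly, very
   poorly drained) versus *well drained* (excessively, somewhat
   excessively, well, moderately well drained), weighted by the length of
   the step that reaches the cell (the pour cell contributes one cell
   size, diagonal steps cell size × √2). The group covering the greater
   length wins: poorly drained → **NRShw**, well drained → **NRMid**.
   Drainage, unlike Ksat, characterizes rather than limits the subsurface
   regime, so the most common condition along the path is the right
   summary.

## Parameters that matter

* **Ksat threshold** (`KSAT_THRESHOLD_DEFAULT`, 5.08 cm h⁻¹): the NRCS
  textural break between very fine sandy loams and sandy loams, separating
  permeable from impermeable flowpath soils. A value exactly at the
  threshold counts as permeable — the published rule states only strict
  inequalities on either side, so the boundary case had to be fixed here;
  permeable is the choice that keeps "impermeable" strict.
* **Patch connectivity** (default 8): wetland pixels joined across ordinal
  and cardinal directions alike, by analogy with the riparian adjacency
  rule, which explicitly counts both. 4-connectivity remains available.
* **Cell size** (default 30 m): the resolution of the national land-cover
  and hydrography products the pipeline mirrors; a pixel is 900 m², so a
  single-pixel wetland is 0.0009 km².
* **Tie-breaks**, all deterministic and documented at the function level:
  pour-point ties go to the smallest (row, col) in row-major order;
  drainage length ties go to poorly drained (the conservative choice toward
  more frequent surface connection); dominant-class ties in catchment
  summaries follow decreasing connectivity (Riparian first).
* **Flow accumulation convention**: counts include the cell itself, so the
  minimum is 1. Only the ranking matters downstream (the pour point is an
  argmax), and any constant offset is rank-preserving; the convention is
  documented rather than attributed to any data product.

Failure taxonomy: every way a unit can fail to classify is recorded in a
`terminal` code (`exited_grid`, `hit_nodata`, `loop_detected`, `max_steps`,
`no_pour_point`, `no_catchment`, `soil_data_error`, missing soils with
`reached_stream`). The Unclassified category is thus auditable, and no
failure ever aborts a batch.

## Watershed summaries

Local percentages divide class wetland area by catchment area. Watershed
(accumulated) percentages sum wetland and land areas over the catchment and
everything upstream *before* dividing. Averaging percentages would weight a
small headwater equally with a large valley catchment; only area-weighting
makes the accumulated percentage well defined, and it is conservative: the
outlet watershed's wetland area equals the sum of all local wetland areas
in the tree.

## The synthetic landscape generator

Real inputs at national scale are far beyond a test suite, so the generator
builds internally consistent bundles with known answers: terrain → flow
direction → accumulation → streams → catchments → wetlands → soils, plus a
truth table. Its postcondition is the package's strongest test: running the
full classifier on a bundle must reproduce the recorded intended class of
every wetland, exactly, for every seed.

The default terrain is an eastward-tilted plane with bounded uniform noise.
The noise half-range (0.002 of the relief) is kept below (√2 − 1)/(2(√2 + 1))
≈ 0.086 of the per-column drop, which guarantees analytically that the
eastward neighbor is always the steepest descent. Two consequences: the
terrain is pit-free by construction (no DEM conditioning needed, which the
package deliberately does not implement), and every flowpath is
row-parallel, so the soil recipe painted along one wetland's path can never
contaminate another's classification. Wetlands are placed at least four
rows apart with growth confined to one row above/below the anchor, and
growth only adds cells with strictly lower accumulation than the anchor, so
the anchor is provably the pour point. Soil recipes encode one class each:
NRShw paints the path poorly drained; NRMid paints it well drained and
permeable (the neutral background, painted explicitly); NRDeep paints the
pour cell's Ksat to 2 cm h⁻¹ — a cell unique to that wetland; Unclassified
erases Ksat and drainage along the path so soil evidence is absent.

What the generator does *not* emulate: convergent (dendritic) drainage,
braided or discontinuous streams, spatially correlated soils, land-cover
classification error, and wetlands whose pour point is interior rather than
downslope. Passing the synthetic battery therefore demonstrates the
*algorithms* are correct under controlled conditions; it says nothing about
input-data quality on real landscapes. Cross-catchment flowpath extension —
rare under the parallel-flow default geometry — is exercised separately by
hand-built grids in the unit tests, as is the diagonal step-length
weighting. A second, fully hand-written 12 × 12 fixture family (one wetland
per class plus an engineered nodata-flowpath failure) lives in
`inst/extdata/handmade_12x12/` with every grid value printed, as
human-auditable ground truth independent of the generator.

Scenario grids default to 40 × 40 cells at 30 m with five wetlands: large
enough for multi-catchment landscapes with distinct flowpath corridors,
small enough that a twenty-scenario battery runs in seconds.

## The water-quality assessment

The assessment pipeline runs in a fixed, logged order: censored-row removal
→ response transformation → standardization → collinearity screen → mixed
model fit → backward selection → slope extraction.

* **Censoring**: constituents whose residual plots show zero/detection-limit
  stripes (TSS, Al, NO₃) have those rows removed; the detection-limit values
  are configuration, never inferred automatically.
* **Transforms**: natural log for every constituent except pH, which is
  raised to the fourth power (pH is already logarithmic; the quartic meets
  residual normality) and is exempt from the log positivity precondition.
* **Standardization** to mean 0, SD 1 of responses and predictors makes
  slopes comparable across constituents whose raw ranges span orders of
  magnitude: a standardized slope of 0.5 reads as half an SD of response
  per SD of predictor. The mean/SD ledger is retained for
  back-transformation.
* **Collinearity**: VIF_j = 1/(1 − R²_j); values at or above 2 raise a flag
  but are not fatal.
* **Mixed model**: REML via `lme4::lmer`, with the four class percentages
  always among the fixed effects and candidate random intercept/slopes by
  region. Random terms enter *uncorrelated* — `(1|g) + (0 + x|g)` — rather
  than `lmer`'s default correlated block. This was a genuinely open design
  point: with few regions and many slopes the correlated maximal fit is
  fragile, and term-wise elimination needs each random slope to be
  independently removable by a one-degree-of-freedom likelihood-ratio test.
* **Backward selection**: random terms first (REML LRTs, no boundary
  correction — a documented simplification that makes the tests slightly
  conservative), then fixed covariates (ML refits, since REML likelihoods
  are not comparable across fixed structures; a covariate's surviving
  random slope is removed with it, a 2-df test). The four class terms are
  never candidates. With fewer than two region levels the model reduces to
  ordinary least squares — the degenerate grouping limit.
* **Grouping choice**: candidate region groupings are compared by AIC of ML
  fits; the minimum wins.
* **Significance**: a slope is flagged when |estimate| > 2 × SE, i.e. the
  ±2 SE interval excludes zero.

The companion simulator (`simulate_wq`) draws right-skewed class
percentages (scaled Beta(0.8, 8): most watersheds hold little wetland area,
a few hold much), standardizes them, and builds the response from the same
model family the fit assumes, with stored ground truth. Its noise defaults —
random-intercept SD 0.3, random-slope SD 0.05, residual SD 0.7 on
standardized scales — encode modest regional slope variation, consistent
with selection often finding random class components unnecessary. The
parameter-recovery battery (slopes 0.4/0.2/0.1/−0.2, n = 1500 sites, nine
regions) checks that each class estimate falls within 2 SE of truth in at
least 90% of replicates; the rate is measured over 400 replicates so its
Monte-Carlo error (≈1.3%) is small against the margin. One honest caveat
surfaced by this battery: with nine regions and a small true slope
variance, roughly half the REML fits are boundary-singular and the 2 SE
intervals cover at ~92–93% rather than the nominal ~95% — a known
few-groups effect (a t₈ interval would need ≈2.3 SE). The package reports
the SEs as they are rather than inflating them.

## Numerical and degenerate-input choices

* Alignment (shape, cell size, origin) is checked up front and mismatches
  are errors — never silent resampling.
* Flow-direction cycles are detected by Kahn's algorithm before
  accumulation and raised as errors naming a cell on the cycle; tracing
  flags loops per path instead.
* Flow onto a nodata cell simply leaves the network; nodata soil cells are
  skipped in aggregation, and an all-nodata path yields Unclassified
  rather than an error.
* Pits and flats in `d8_from_dem` become nodata rather than being filled;
  DEM conditioning is out of scope.
* `max_steps` for tracing defaults to the grid cell count, making
  non-termination impossible.
* Wetland pixels on nodata catchments are retained and routed to
  Unclassified rather than dropped.

## Limitations

The classification is structural and qualitative: no travel times, no flow
frequencies, no hydrologic alterations (ditches, tile drains), no
functional (climate-driven) connectivity, and no separation of lakes and
estuaries from streams within the open-water class. The flowpath tracer is
pure D8 steepest descent; tools that route around obstacles by cost
surfaces can differ. WetIds are unique only within a processing unit.
Rasters are exchanged as single-band ESRI ASCII grids; projection handling
and resampling are out of scope, and inputs must be pre-aligned.
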