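# wetconnect

Wetland hydrologic connectivity classification for raster landscapes, with a
standardized mixed-effects assessment of how watershed wetland-connectivity
composition relates to stream water quality.

## The problem

Wetlands influence downstream water quality through the hydrologic pathways
that connect them to streams, but connectivity is rarely quantified at
landscape scale. `wetconnect` implements a structural classification that
places every wetland on a connectivity gradient using only nationally
available raster inputs — land cover, D8 flow direction and accumulation,
catchment boundaries, rasterized stream lines, soil saturated hydraulic
conductivity (Ksat) and NRCS soil drainage class — and then summarizes and
statistically assesses the result. It is written for landscape
ecohydrologists and water-quality modelers who want the classification, the
watershed summaries and the regression machinery reproducible from code.

## The classification

Wetland pixels (land-cover codes 90, woody; 95, emergent herbaceous) are
grouped into 8-connected patches, subdivided at hydrologic catchment
boundaries into wetland units, and each unit gets a pour point: its pixel of
maximum flow accumulation. Classes are assigned by the decision flow:

1. **Riparian** — the pour point lies within one pixel (cardinal or ordinal)
   of a *buffered stream* cell (union of open-water land cover and
   rasterized stream lines). Soils are not consulted.
2. Otherwise the D8 flowpath is traced from the pour point, across
   catchment boundaries, until it meets a buffered stream. Along the path:
   * min Ksat < 5.08 cm h⁻¹ → **NRDeep** (impermeable flowpath; deep
     subsurface flow, rare fill-and-spill surface connections);
   * min Ksat ≥ 5.08 cm h⁻¹ and length-majority drainage *poorly drained* →
     **NRShw** (shallow subsurface flow, saturation-excess overland flow);
   * min Ksat ≥ 5.08 cm h⁻¹ and *well drained* → **NRMid** (mid-depth
     subsurface flow, infiltration-excess overland flow).
3. Units with no usable flowpath or no soil data are **Unclassified**.

5.08 cm h⁻¹ is the NRCS textural threshold between very fine sandy loams
and sandy loams; the minimum is used because the least permeable soil limits
flow, while drainage class uses the greatest-length rule because it
characterizes, rather than limits, the subsurface regime. Connectivity ranks
Riparian > NRShw > NRMid > NRDeep; "depth" refers to the flowpath, not the
wetland.

Classified units are summarized per catchment (percent of area per class,
dominant class) and accumulated over watersheds by summing areas upstream
before dividing — percentages are never averaged.

The water-quality side fits standardized linear mixed-effects models of
in-stream constituents on the four watershed class percentages (natural-log
responses, pH⁴ for pH; predictors and responses standardized to mean 0,
SD 1), with region-varying random intercepts and slopes, backward selection
(random terms first, then fixed covariates, LRT at α = 0.05) that always
retains the four class terms, and extraction of standardized population-mean
slopes ± 2 standard errors.

## Worked example

Generate a synthetic landscape with one wetland of each class, classify it,
and summarize:

```r
library(wetconnect)

b <- generate_scenario(seed = 7)            # 40 x 40 grid, 30 m cells
v <- verify_scenario(b)
v$truth[, c("anchor_row", "anchor_col", "intended_class", "assigned_class")]
#>   anchor_row anchor_col intended_class assigned_class
#> 1          3         31       Riparian       Riparian
#> 2         12         29          NRShw          NRShw
#> 3         20         29          NRMid          NRMid
#> 4         29         29         NRDeep         NRDeep
#> 5         38         29   Unclassified   Unclassified

subset(v$records, select = c(wet_id, class, min_ksat, drainage_majority,
                             path_length_m, terminal))
```

Each row is one wetland unit: the NRDeep unit shows `min_ksat = 2` (painted
below the 5.08 cm h⁻¹ threshold at its outlet), the NRShw unit a poorly
drained flowpath majority, and the engineered Unclassified unit has no soil
data along its path. The same run is available from the shell via the thin
CLI (`inst/cli/wetconnect.R`): `synth`, `delineate`, `streams`, `classify`,
`summarize`, `wq-sim`, `wq-fit`, `run`, `check-align`.

On the published national per-class totals shipped in
`inst/extdata/conus_class_totals.csv`, `summary_statistics()` reproduces the
headline arithmetic: 6,662,993 wetland units in total, a mean Riparian
wetland area of 0.11 km², and a Riparian:NRDeep mean-area ratio of 5.5 at
printed precision.

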