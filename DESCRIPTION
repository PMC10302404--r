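Package: wetconnect
Title: Wetland Hydrologic Connectivity Classification for Raster Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies freshwater wetlands into four hydrologic connectivity
    classes (riparian, non-riparian shallow, mid-depth and deep) from aligned
    raster layers: wetland patches are delineated from a land-cover grid,
    subdivided by hydrologic catchment, given pour points at their maximum
    flow-accumulation pixel, and traced along D8 flowpaths to a buffered
    stream layer; saturated hydraulic conductivity and soil drainage class
    aggregated along each flowpath drive the class assignment. Includes
    catchment and watershed summaries of class percentages, a synthetic
    landscape generator with known ground truth for end-to-end testing, and a
    standardized linear mixed-effects assessment (random slopes by region,
    backward selection with forced retention of the class terms) linking
    watershed class percentages to stream water-quality constituents.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    optparse,
    withr
Config/testthat/edition: 3
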