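Hand-written 12 x 12 synthetic fixture landscape (30 m cells).

Every value is printed in the .asc files so the expected outcome can be
audited by eye, independently of the programmatic scenario generator.

Layout (rows top to bottom, cols left to right, 1-based):
- Flow direction is uniformly east (code 1) in columns 1-11; column 12 and
  the single cell (10,8) are nodata.
- The stream is column 12: rasterized stream line in every row, and also
  open water (land cover 11) in rows 1-6 (provenance "both" there, "line
  only" in rows 7-12).
- Catchment 1 = rows 1-6, catchment 2 = rows 7-12; topology.csv routes 1 -> 2.
- Soils default to Ksat 10 cm/h and drainage class 3 (well drained).

Wetlands (land-cover codes 90/95) and their intended classes:
- rows  2, cols 10-11: pour point (2,11) adjacent to the stream -> Riparian
- row   4, cols  3-4: flowpath (4,4)..(4,11) painted drainage 6 (poorly
  drained), Ksat 10 -> NRShw
- row   6, cols  3-4: flowpath on default well-drained permeable soils
  -> NRMid
- row   8, cols  3-4: pour cell (8,4) Ksat 2 cm/h (impermeable) -> NRDeep
- row  10, cols  4-5: flowpath runs into the nodata flow-direction cell at
  (10,8) before reaching the stream -> Unclassified

truth.csv lists each wetland's pour point and intended class.
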