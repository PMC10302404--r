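# The "buffered streams" target layer: union of open-water land-cover pixels
# (which give width to rivers wide enough to be detected in imagery) and a
# rasterized stream-line grid (which supplies narrow streams). Provenance is
# kept per cell for diagnostics.

#' Build the buffered streams layer
#'
#' @param landcover Categorical `raster_grid`; open water is code 11 by
#'   default.
#' @param stream_raster `raster_grid` in which any nonzero, non-nodata cell
#'   marks a rasterized stream line.
#' @param water_code Open-water land-cover code.
#' @return A `raster_grid` (`layer_kind` `"stream"`) of provenance codes:
#'   0 = not stream, 1 = water pixel only, 2 = stream line only, 3 = both.
#'   Use [stream_mask()] for the plain boolean view.
#' @export
build_buffered_streams <- function(landcover, stream_raster, water_code = 11) {
  check_alignment(landcover, stream_raster)
  water <- !is.na(landcover$values) & landcover$values == water_code
  line <- !is.na(stream_raster$values) & stream_raster$values != 0
  prov <- matrix(0L, nrow(water), ncol(water))
  prov[water] <- 1L
  prov[line] <- prov[line] + 2L
  raster_grid(prov, cell_size = landcover$cell_size,
              origin = landcover$origin, nodata = landcover$nodata,
              layer_kind = "stream")
}

#' Boolean view of a buffered-streams layer
#'
#' @param streams Provenance grid from [build_buffered_streams()], or any
#'   grid where nonzero marks stream.
#' @return Logical matrix.
#' @export
stream_mask <- function(streams) {
  v <- if (inherits(streams, "raster_grid")) streams$values else streams
  !is.na(v) & v != 0
}

#' Riparian adjacency test
#'
#' A wetland is riparian when its pour point lies within one pixel — ordinal
#' and cardinal directions alike, i.e. Chebyshev distance <= 1 — of a
#' buffered-stream cell. A pour point sitting on a stream cell (distance 0)
#' counts as riparian: a wetland overlapping mapped water is maximally
#' connected.
#'
#' @param pour_point Integer `c(row, col)`.
#' @param streams Buffered-streams layer (provenance grid or boolean).
#' @return `TRUE` or `FALSE`.
#' @export
is_riparian_adjacent <- function(pour_point, streams) {
  s <- stream_mask(streams)
  nr <- nrow(s); nc <- ncol(s)
  r <- pour_point[1]; c <- pour_point[2]
  if (r < 1 || r > nr || c < 1 || c > nc)
    stop(sprintf("pour point (%d, %d) outside grid", r, c))
  rw <- max(1, r - 1):min(nr, r + 1)
  cw <- max(1, c - 1):min(nc, c + 1)
  any(s[rw, cw])
}
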