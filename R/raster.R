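# Core grid data model shared by every spatial layer in the pipeline.
# All layers in one analysis must be pixel-aligned: same shape, cell size
# and upper-left origin. Nodata is represented internally as NA; the
# `nodata` field only records the sentinel used on disk.

#' D8 flow-direction code table
#'
#' The eight single-flow-direction codes used throughout the package, in the
#' ESRI/NHDPlus powers-of-two convention: 1 = E, 2 = SE, 4 = S, 8 = SW,
#' 16 = W, 32 = NW, 64 = N, 128 = NE. This is the one place the mapping is
#' defined; `d8_offset()` exposes the row/column step for a code.
#'
#' @format Integer vector of length 8.
#' @export
D8_CODES <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)

# row/col offsets, index-matched to D8_CODES (rows grow downward/south)
.d8_drow <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.d8_dcol <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Row/column offset of a D8 code
#'
#' @param code One of the eight D8 codes.
#' @return Integer vector `c(drow, dcol)`.
#' @export
d8_offset <- function(code) {
  k <- match(code, D8_CODES)
  if (is.na(k)) stop("not a D8 code: ", code)
  c(.d8_drow[k], .d8_dcol[k])
}

#' Construct a raster grid
#'
#' A lightweight in-memory raster: a matrix of values plus the georeferencing
#' needed to keep layers aligned. Rows run north to south (row 1 is the top
#' edge), columns west to east. Nodata cells are stored as `NA`.
#'
#' @param values Numeric or logical matrix (at least 1 x 1).
#' @param cell_size Pixel edge length in metres (> 0); 30 m is the working
#'   resolution of the national land-cover and hydrography grids this
#'   pipeline mirrors.
#' @param origin Numeric `c(x, y)` of the upper-left corner in projected
#'   coordinates.
#' @param nodata Sentinel value used when the grid is written to disk.
#' @param layer_kind Free tag naming what the layer holds (e.g. `"landcover"`,
#'   `"flowdir"`, `"accumulation"`, `"catchment"`, `"ksat"`, `"drainage"`,
#'   `"stream"`, `"label"`).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 30, origin = c(0, 0),
                        nodata = -9999, layer_kind = "generic") {
  if (!is.numeric(values) && !is.logical(values))
    stop("`values` must be a numeric or logical matrix")
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid must be at least 1 x 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2 || !is.numeric(origin))
    stop("`origin` must be numeric c(x, y)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata,
         layer_kind = layer_kind),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid [%s]> %d x %d, cell %g m, origin (%g, %g), %d nodata\n",
              x$layer_kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Check that raster layers are pixel-aligned
#'
#' All layers entering one analysis must share shape, cell size and origin;
#' a mismatch is an error, not a warning, because silently resampled layers
#' corrupt every per-pixel rule downstream.
#'
#' @param ... `raster_grid` objects (or one list of them).
#' @param tol Numeric tolerance on cell size and origin.
#' @return Invisibly `TRUE`; stops with a message naming the mismatch.
#' @export
check_alignment <- function(..., tol = 1e-6) {
  grids <- list(...)
  if (length(grids) == 1 && !inherits(grids[[1]], "raster_grid"))
    grids <- grids[[1]]
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (g in grids) {
    if (!inherits(g, "raster_grid")) stop("all inputs must be raster_grid objects")
    if (!identical(dim(g$values), dim(ref$values)))
      stop(sprintf("alignment error: layer '%s' is %d x %d but '%s' is %d x %d",
                   g$layer_kind, nrow(g$values), ncol(g$values),
                   ref$layer_kind, nrow(ref$values), ncol(ref$values)))
    if (abs(g$cell_size - ref$cell_size) > tol)
      stop(sprintf("alignment error: cell size %g ('%s') != %g ('%s')",
                   g$cell_size, g$layer_kind, ref$cell_size, ref$layer_kind))
    if (any(abs(g$origin - ref$origin) > tol))
      stop(sprintf("alignment error: origin of '%s' differs from '%s'",
                   g$layer_kind, ref$layer_kind))
  }
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by the values in
#' row order, top row first. The nodata sentinel is converted to `NA`.
#'
#' @param path File path.
#' @param layer_kind Tag stored on the returned grid.
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, layer_kind = "generic") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (f in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[f]])) stop("ascii grid header missing field: ", f)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("ascii grid body has %d values, expected %d", length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  raster_grid(m, cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
              nodata = nodata, layer_kind = layer_kind)
}

#' Write an ESRI ASCII grid
#'
#' @param grid A `raster_grid`. `NA` cells are written as the grid's nodata
#'   sentinel.
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  nodata <- grid$nodata
  if (is.na(nodata)) nodata <- -9999
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
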