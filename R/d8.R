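# D8 hydrologic primitives: downstream stepping, flow accumulation,
# steepest-descent flow direction, connected-component labeling.

# internal: linear (column-major) index helpers on an nr x nc grid
.cell_index <- function(row, col, nr) (col - 1L) * nr + row

# internal: vector of downstream linear indices for a flow-direction grid.
# NA where the code is nodata, the step leaves the grid, or the target cell
# is itself nodata (water exiting onto nodata simply leaves the network).
.downstream_index <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  idx <- seq_len(n)
  k <- match(as.vector(v), D8_CODES)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  tr <- rr + .d8_drow[k]
  tc <- cc + .d8_dcol[k]
  ok <- !is.na(k) & !is.na(tr) & tr >= 1L & tr <= nr & tc >= 1L & tc <= nc
  ds <- rep(NA_integer_, n)
  ds[ok] <- .cell_index(tr[ok], tc[ok], nr)
  ds
}

#' Downstream neighbor of a cell under D8 flow directions
#'
#' @param fdr A `raster_grid` of D8 codes (see [D8_CODES]).
#' @param cell Integer `c(row, col)`, 1-based.
#' @return Integer `c(row, col)` of the single downstream neighbor, or `NULL`
#'   if the cell's code is nodata or the step leaves the grid.
#' @export
downstream_neighbor <- function(fdr, cell) {
  v <- fdr$values
  nr <- nrow(v); nc <- ncol(v)
  r <- cell[1]; c <- cell[2]
  if (r < 1 || r > nr || c < 1 || c > nc)
    stop(sprintf("cell (%d, %d) outside %d x %d grid", r, c, nr, nc))
  code <- v[r, c]
  k <- match(code, D8_CODES)
  if (is.na(k)) return(NULL)
  tr <- r + .d8_drow[k]; tc <- c + .d8_dcol[k]
  if (tr < 1 || tr > nr || tc < 1 || tc > nc) return(NULL)
  c(tr, tc)
}

#' D8 flow accumulation
#'
#' Counts, for every cell, the number of cells draining to it through D8
#' links, including the cell itself — the minimum value is therefore 1. Only
#' the ranking of accumulation values is consumed downstream (pour points are
#' accumulation argmaxes), so the self-inclusive convention is a benign,
#' documented choice. Nodata cells stay nodata; flow onto a nodata cell
#' leaves the network.
#'
#' @param fdr A `raster_grid` of D8 codes. Must be acyclic over its non-nodata
#'   cells; a cycle is an error naming one cell on it.
#' @return A `raster_grid` of accumulation counts (`layer_kind`
#'   `"accumulation"`).
#' @export
flow_accumulation <- function(fdr) {
  v <- fdr$values
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  valid <- !is.na(match(as.vector(v), D8_CODES))
  ds <- .downstream_index(v)
  # drop links whose target is nodata
  ds[!is.na(ds) & !valid[ifelse(is.na(ds), 1L, ds)]] <- NA_integer_
  indeg <- tabulate(ds[!is.na(ds)], nbins = n)
  acc <- rep(NA_real_, n)
  acc[valid] <- 1
  queue <- which(valid & indeg == 0L)
  qlen <- length(queue)
  queue <- c(queue, integer(n))
  head <- 1L
  processed <- 0L
  while (head <= qlen) {
    i <- queue[head]; head <- head + 1L
    processed <- processed + 1L
    d <- ds[i]
    if (!is.na(d)) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) {
        qlen <- qlen + 1L
        queue[qlen] <- d
      }
    }
  }
  if (processed < sum(valid)) {
    bad <- which(valid & indeg > 0L)[1]
    stop(sprintf("cycle detected in flow directions at cell (%d, %d)",
                 ((bad - 1L) %% nr) + 1L, ((bad - 1L) %/% nr) + 1L))
  }
  raster_grid(matrix(acc, nr, nc), cell_size = fdr$cell_size,
              origin = fdr$origin, nodata = fdr$nodata,
              layer_kind = "accumulation")
}

#' Derive D8 flow directions from a DEM
#'
#' Each cell points to its steepest-descent neighbor, with drop measured per
#' unit distance (diagonal distance is `cell_size * sqrt(2)`). Ties are broken
#' by the fixed code order 1, 2, 4, ..., 128. Cells with no strictly lower
#' neighbor (pits and flats) become nodata rather than being filled; the
#' synthetic terrain generator is responsible for producing pit-free surfaces.
#'
#' @param dem A numeric `raster_grid`.
#' @return A `raster_grid` of D8 codes (`layer_kind` `"flowdir"`).
#' @export
d8_from_dem <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  dist <- ifelse(.d8_drow != 0L & .d8_dcol != 0L, sqrt(2), 1) * dem$cell_size
  best_drop <- matrix(0, nr, nc)           # require strictly positive drop
  best_code <- matrix(NA_real_, nr, nc)
  for (k in seq_along(D8_CODES)) {
    zn <- matrix(NA_real_, nr, nc)
    sr <- (1 + max(0, -.d8_drow[k])):(nr - max(0, .d8_drow[k]))
    sc <- (1 + max(0, -.d8_dcol[k])):(nc - max(0, .d8_dcol[k]))
    zn[sr, sc] <- z[sr + .d8_drow[k], sc + .d8_dcol[k]]
    drop <- (z - zn) / dist[k]
    upd <- !is.na(drop) & drop > best_drop   # strict > keeps first code on ties
    best_drop[upd] <- drop[upd]
    best_code[upd] <- D8_CODES[k]
  }
  best_code[is.na(z)] <- NA_real_
  raster_grid(best_code, cell_size = dem$cell_size, origin = dem$origin,
              nodata = dem$nodata, layer_kind = "flowdir")
}

#' Label connected patches in a boolean mask
#'
#' Breadth-first connected-component labeling. Labels are dense from 1 in
#' column-major scan order of each component's first-seen cell; false (and
#' `NA`) cells get label 0. The default 8-connectivity treats ordinal and
#' cardinal neighbors alike, matching the adjacency convention used for the
#' riparian test; 4-connectivity is available as an option.
#'
#' @param mask A logical `raster_grid` (or numeric; nonzero is true).
#' @param connectivity 4 or 8.
#' @return A `raster_grid` of integer labels (`layer_kind` `"label"`).
#' @export
label_patches <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- mask$values
  nr <- nrow(v); nc <- ncol(v)
  n <- nr * nc
  truecell <- !is.na(v) & (v != 0)
  if (connectivity == 8) {
    drow <- .d8_drow; dcol <- .d8_dcol
  } else {
    card <- .d8_dcol == 0L | .d8_drow == 0L
    drow <- .d8_drow[card]; dcol <- .d8_dcol[card]
  }
  labels <- integer(n)
  stack <- integer(n)
  next_label <- 0L
  for (seed in seq_len(n)) {
    if (!truecell[seed] || labels[seed] != 0L) next
    next_label <- next_label + 1L
    labels[seed] <- next_label
    stack[1] <- seed
    top <- 1L
    while (top > 0L) {
      i <- stack[top]; top <- top - 1L
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (k in seq_along(drow)) {
        tr <- r + drow[k]; tc <- cc + dcol[k]
        if (tr < 1L || tr > nr || tc < 1L || tc > nc) next
        j <- .cell_index(tr, tc, nr)
        if (truecell[j] && labels[j] == 0L) {
          labels[j] <- next_label
          top <- top + 1L
          stack[top] <- j
        }
      }
    }
  }
  raster_grid(matrix(labels, nr, nc), cell_size = mask$cell_size,
              origin = mask$origin, nodata = mask$nodata, layer_kind = "label")
}
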