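# Synthetic landscape generation: internally consistent input bundles
# (terrain -> flow direction/accumulation -> streams -> catchments ->
# wetlands -> soils) with recorded ground-truth classes, so every spatial
# module is testable end to end without external data.
#
# The default terrain is an eastward-tilted plane with small bounded noise:
# steepest descent is strictly eastward, accumulation grows along each row,
# and the stream forms as a band of high-accumulation columns. Each placed
# wetland then owns a row-parallel flowpath disjoint from every other
# wetland's, so the soil recipe painted along one path can never contaminate
# another wetland's classification. The generator verifies its own
# postcondition: classifying the bundle must reproduce the recorded truth.

#' Generate pit-free synthetic terrain
#'
#' An eastward-decreasing plane plus seeded uniform noise. The result is
#' rejected and redrawn (up to `max_tries`) until every non-edge cell has a
#' strictly lower 8-neighbor, guaranteeing D8 validity without any DEM
#' conditioning.
#'
#' @param seed Integer RNG seed.
#' @param shape Integer `c(rows, cols)`, at least 4 x 4.
#' @param cell_size Pixel edge, metres.
#' @param relief Vertical range of the tilted plane, metres.
#' @param noise_amplitude Noise half-range as a fraction of `relief`. The
#'   default 0.002 keeps the noise half-range below `(sqrt(2) - 1) /
#'   (2 * (sqrt(2) + 1))` (~ 0.086) of the per-column drop, which guarantees
#'   the eastward neighbor is always the steepest descent; flowpaths then
#'   stay row-parallel and placed wetlands cannot share path cells.
#' @param max_tries Redraw budget before erroring.
#' @return A `raster_grid` DEM. Sets the RNG via `set.seed(seed)`.
#' @export
generate_terrain <- function(seed, shape = c(40, 40), cell_size = 30,
                             relief = 40, noise_amplitude = 0.002,
                             max_tries = 20) {
  stopifnot(shape[1] >= 4, shape[2] >= 4)
  nr <- shape[1]; nc <- shape[2]
  base <- matrix(rep(relief * (nc - seq_len(nc)) / (nc - 1), each = nr), nr, nc)
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    noise <- matrix(stats::runif(nr * nc, -1, 1) * noise_amplitude * relief,
                    nr, nc)
    z <- base + noise
    if (.is_pit_free(z)) {
      return(raster_grid(z, cell_size = cell_size, layer_kind = "dem"))
    }
  }
  stop("could not generate pit-free terrain in ", max_tries,
       " tries; reduce noise_amplitude")
}

# every non-edge cell has a strictly lower 8-neighbor
.is_pit_free <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) return(TRUE)
  lower <- matrix(FALSE, nr, nc)
  for (k in seq_along(D8_CODES)) {
    zn <- matrix(NA_real_, nr, nc)
    sr <- (1 + max(0, -.d8_drow[k])):(nr - max(0, .d8_drow[k]))
    sc <- (1 + max(0, -.d8_dcol[k])):(nc - max(0, .d8_dcol[k]))
    zn[sr, sc] <- z[sr + .d8_drow[k], sc + .d8_dcol[k]]
    lower <- lower | (!is.na(zn) & zn < z)
  }
  all(lower[2:(nr - 1), 2:(nc - 1)])
}

#' Derive flow direction, accumulation and stream lines from a DEM
#'
#' @param dem Pit-free `raster_grid` DEM.
#' @param stream_threshold Accumulation count at or above which a cell is a
#'   stream line.
#' @return List of `raster_grid`s: `fdr`, `accumulation`, `streamlines`
#'   (0/1).
#' @export
derive_hydrology <- function(dem, stream_threshold) {
  fdr <- d8_from_dem(dem)
  acc <- flow_accumulation(fdr)
  s <- matrix(0L, nrow(acc$values), ncol(acc$values))
  s[!is.na(acc$values) & acc$values >= stream_threshold] <- 1L
  list(fdr = fdr, accumulation = acc,
       streamlines = raster_grid(s, cell_size = dem$cell_size,
                                 origin = dem$origin, nodata = dem$nodata,
                                 layer_kind = "streamlines"))
}

#' Split streams into segments and assign catchments
#'
#' Stream cells are split into `n_catchments` contiguous row bands; every
#' land cell is assigned to the segment its D8 walk first reaches; cells
#' whose walk exits the grid without touching a stream get nodata catchment.
#' The from-to topology is derived from stream-cell flow directions (an edge
#' where one segment's flow steps into another's) and checked acyclic.
#'
#' @param fdr D8 `raster_grid`.
#' @param streamlines 0/1 `raster_grid`.
#' @param n_catchments Number of segments; must not exceed the number of
#'   distinct stream rows.
#' @return List: `catchments` (`raster_grid`), `topology` (`data.frame` of
#'   `from`, `to`).
#' @export
generate_catchments <- function(fdr, streamlines, n_catchments = 3) {
  s <- stream_mask(streamlines)
  if (!any(s)) stop("no stream cells to segment")
  stream_rows <- sort(unique(which(s, arr.ind = TRUE)[, 1]))
  if (n_catchments > length(stream_rows))
    stop("n_catchments (", n_catchments, ") exceeds available stream rows (",
         length(stream_rows), ")")
  band <- if (n_catchments == 1) rep(1L, length(stream_rows))
          else cut(seq_along(stream_rows), n_catchments, labels = FALSE)
  row_seg <- stats::setNames(band, stream_rows)
  nr <- nrow(s); nc <- ncol(s)
  seg <- matrix(NA_real_, nr, nc)
  for (r in stream_rows) seg[r, s[r, ]] <- row_seg[[as.character(r)]]
  # propagate: each land cell takes the catchment of its downstream cell
  ds <- .downstream_index(fdr$values)
  catch <- as.vector(seg)
  repeat {
    todo <- which(is.na(catch) & !is.na(ds))
    if (length(todo) == 0) break
    new <- catch[ds[todo]]
    fill <- !is.na(new)
    if (!any(fill)) break
    catch[todo[fill]] <- new[fill]
  }
  topo <- NULL
  scells <- which(as.vector(s))
  for (i in scells) {
    d <- ds[i]
    if (!is.na(d) && !is.na(seg[d]) && seg[d] != seg[i])
      topo <- rbind(topo, c(seg[i], seg[d]))
  }
  topology <- if (is.null(topo)) {
    data.frame(from = numeric(0), to = numeric(0))
  } else {
    unique(data.frame(from = topo[, 1], to = topo[, 2]))
  }
  # acyclicity check via the watershed accumulator's own Kahn pass
  if (nrow(topology) > 0) {
    dummy <- data.frame(catchment_id = sort(unique(c(topology$from, topology$to))),
                        local_area_km2 = 1)
    for (cl in CONNECTIVITY_CLASSES) dummy[[paste0("area_", cl)]] <- 0
    accumulate_watershed(dummy, topology)   # stops on a cycle
  }
  list(catchments = raster_grid(matrix(catch, nr, nc),
                                cell_size = fdr$cell_size, origin = fdr$origin,
                                nodata = fdr$nodata, layer_kind = "catchment"),
       topology = topology)
}

# neutral soil defaults: permeable and well drained, so each wetland's class
# is controlled entirely by its own painted recipe
.NEUTRAL_KSAT <- 10
.NEUTRAL_DRAINAGE <- 3   # well drained

#' Place a wetland with an intended connectivity class
#'
#' Grows a wetland 8-connected from `anchor` (which becomes the pour point:
#' growth only adds cells with strictly lower accumulation), sets land-cover
#' codes, and paints the soil recipe that realises `intended_class` along
#' the traced flowpath:
#' * `Riparian`: anchor within one pixel of a stream; soils untouched.
#' * `NRShw`: flowpath drainage painted poorly drained, Ksat left permeable.
#' * `NRMid`: flowpath painted well drained and permeable (the neutral
#'   background, painted explicitly).
#' * `NRDeep`: the pour-point cell's Ksat painted below the permeability
#'   threshold (the pour cell is on the path and unique to this wetland).
#' * `Unclassified`: flowpath Ksat and drainage painted nodata, so soil
#'   evidence is absent.
#'
#' @param bundle Scenario bundle under construction (list of grids; see
#'   [generate_scenario()]).
#' @param anchor Integer `c(row, col)` on land.
#' @param n_pixels Wetland size in pixels.
#' @param intended_class One of [CONNECTIVITY_CLASSES].
#' @return Updated bundle; its `truth` table gains a row (`anchor_row`,
#'   `anchor_col`, `intended_class`).
#' @export
place_wetland <- function(bundle, anchor, n_pixels, intended_class) {
  s <- stream_mask(bundle$streamlines)
  acc <- bundle$accumulation$values
  lc <- bundle$landcover$values
  nr <- nrow(lc); nc <- ncol(lc)
  r0 <- anchor[1]; c0 <- anchor[2]
  if (s[r0, c0] || lc[r0, c0] %in% c(90, 95))
    stop("placement error: anchor not on available land")
  cheb <- .chebyshev_to_stream(anchor, s)
  if (intended_class == "Riparian") {
    if (cheb > 1) stop("placement error: Riparian anchor not adjacent to stream")
  } else {
    if (cheb < 2) stop("placement error: non-riparian anchor within one pixel of stream")
  }
  catch0 <- bundle$catchments$values[r0, c0]
  # grow 8-connected among cells with lower accumulation than the anchor,
  # same catchment, off-stream, within one row of the anchor (keeps the
  # pour point at the anchor and wetlands in separate flow corridors)
  pick <- matrix(c(r0, c0), 1, 2)
  frontier <- pick
  while (nrow(pick) < n_pixels && nrow(frontier) > 0) {
    newf <- NULL
    for (i in seq_len(nrow(frontier))) {
      for (k in seq_along(D8_CODES)) {
        tr <- frontier[i, 1] + .d8_drow[k]; tc <- frontier[i, 2] + .d8_dcol[k]
        if (tr < 1 || tr > nr || tc < 1 || tc > nc) next
        if (abs(tr - r0) > 1) next
        if (s[tr, tc] || lc[tr, tc] %in% c(90, 95)) next
        if (any(pick[, 1] == tr & pick[, 2] == tc)) next
        if (is.na(acc[tr, tc]) || is.na(acc[r0, c0])) next
        if (acc[tr, tc] >= acc[r0, c0]) next
        if (!identical(bundle$catchments$values[tr, tc], catch0)) next
        if (intended_class != "Riparian" &&
            .chebyshev_to_stream(c(tr, tc), s) < 2) next
        pick <- rbind(pick, c(tr, tc))
        newf <- rbind(newf, c(tr, tc))
        if (nrow(pick) >= n_pixels) break
      }
      if (nrow(pick) >= n_pixels) break
    }
    if (is.null(newf)) break
    frontier <- newf
  }
  # alternate woody / emergent herbaceous codes; both are wetland
  codes <- rep(c(95, 90), length.out = nrow(pick))
  lc[pick] <- codes
  bundle$landcover$values <- lc
  if (intended_class != "Riparian") {
    fp <- trace_flowpath(anchor, bundle$fdr, bundle$streamlines)
    if (fp$terminal != "reached_stream")
      stop("placement error: flowpath from anchor did not reach a stream (",
           fp$terminal, ")")
    cells <- fp$cells
    if (intended_class == "NRShw") {
      bundle$drainage$values[cells] <- 6          # poorly drained
      bundle$ksat$values[cells] <- .NEUTRAL_KSAT
    } else if (intended_class == "NRMid") {
      bundle$drainage$values[cells] <- 3          # well drained
      bundle$ksat$values[cells] <- .NEUTRAL_KSAT
    } else if (intended_class == "NRDeep") {
      bundle$ksat$values[r0, c0] <- 2.0           # impermeable at the outlet
    } else if (intended_class == "Unclassified") {
      bundle$ksat$values[cells] <- NA
      bundle$drainage$values[cells] <- NA
    } else stop("unknown intended class: ", intended_class)
  }
  bundle$truth <- rbind(bundle$truth,
                        data.frame(anchor_row = r0, anchor_col = c0,
                                   intended_class = intended_class,
                                   stringsAsFactors = FALSE))
  bundle
}

.chebyshev_to_stream <- function(cell, s) {
  sc <- which(s, arr.ind = TRUE)
  if (nrow(sc) == 0) return(Inf)
  min(pmax(abs(sc[, 1] - cell[1]), abs(sc[, 2] - cell[2])))
}

#' Generate a complete synthetic scenario with known ground truth
#'
#' Builds terrain, hydrology, catchments and one wetland of each requested
#' class, then verifies its own postcondition: running the full classifier
#' on the bundle must reproduce the recorded truth table exactly (matched by
#' pour-point position). A bundle that fails this check is an error, never a
#' silently wrong fixture.
#'
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @param shape Grid shape, default 40 x 40.
#' @param cell_size Pixel edge, metres.
#' @param intents Character vector of intended classes to place, in order.
#' @param n_pixels Wetland sizes (recycled over `intents`).
#' @param n_catchments Stream segments/catchments.
#' @param stream_threshold Accumulation threshold for stream cells; default
#'   `ceiling(0.8 * shape[2])` puts the stream band in the eastern fifth.
#' @param validate Run the classifier postcondition check (default `TRUE`).
#' @return Scenario bundle: aligned grids (`landcover`, `dem`, `fdr`,
#'   `accumulation`, `streamlines`, `catchments`, `ksat`, `drainage`),
#'   `topology`, and `truth` (`anchor_row`, `anchor_col`, `intended_class`).
#' @export
generate_scenario <- function(seed, shape = c(40, 40), cell_size = 30,
                              intents = c("Riparian", "NRShw", "NRMid",
                                          "NRDeep", "Unclassified"),
                              n_pixels = 6, n_catchments = 3,
                              stream_threshold = NULL, validate = TRUE) {
  nr <- shape[1]; nc <- shape[2]
  if (is.null(stream_threshold)) stream_threshold <- ceiling(0.8 * nc)
  dem <- generate_terrain(seed, shape, cell_size)
  hyd <- derive_hydrology(dem, stream_threshold)
  cat <- generate_catchments(hyd$fdr, hyd$streamlines, n_catchments)
  g <- function(vals, kind) raster_grid(vals, cell_size = cell_size,
                                        layer_kind = kind)
  bundle <- list(
    dem = dem, fdr = hyd$fdr, accumulation = hyd$accumulation,
    streamlines = hyd$streamlines, catchments = cat$catchments,
    topology = cat$topology,
    landcover = g(matrix(41, nr, nc), "landcover"),      # forest background
    ksat = g(matrix(.NEUTRAL_KSAT, nr, nc), "ksat"),
    drainage = g(matrix(.NEUTRAL_DRAINAGE, nr, nc), "drainage"),
    truth = data.frame(anchor_row = integer(0), anchor_col = integer(0),
                       intended_class = character(0), stringsAsFactors = FALSE)
  )
  n_pixels <- rep(n_pixels, length.out = length(intents))
  s <- stream_mask(bundle$streamlines)
  rows <- round(seq(3, nr - 2, length.out = max(length(intents), 2)))
  # enforce >= 4-row separation so wetlands and painted paths stay disjoint
  if (length(intents) > 1 && min(diff(rows)) < 4)
    stop("grid too small to separate ", length(intents), " wetlands")
  for (i in seq_along(intents)) {
    r <- rows[i]
    first_stream_col <- which(s[r, ])[1]
    if (is.na(first_stream_col))
      stop("no stream cell in row ", r, "; raise stream_threshold coverage")
    anchor_col <- if (intents[i] == "Riparian") first_stream_col - 1
                  else first_stream_col - 3
    bundle <- place_wetland(bundle, c(r, anchor_col), n_pixels[i], intents[i])
  }
  if (validate) {
    chk <- verify_scenario(bundle)
    if (!chk$ok)
      stop("scenario postcondition failed: ",
           paste(chk$mismatch, collapse = "; "))
  }
  bundle
}

#' Verify a scenario bundle against its truth table
#'
#' Runs delineation and classification on the bundle's grids and matches
#' each truth row to the unit containing its anchor pixel.
#'
#' @param bundle A scenario bundle.
#' @return List: `ok` (logical), `records` (classifier output), `truth`
#'   (truth table joined with assigned classes), `mismatch` (character
#'   vector describing failures).
#' @export
verify_scenario <- function(bundle) {
  del <- delineate_wetlands(bundle$landcover, bundle$catchments,
                            bundle$accumulation)
  streams <- build_buffered_streams(bundle$landcover, bundle$streamlines)
  records <- classify_all(del$units,
                          list(fdr = bundle$fdr, streams = streams,
                               ksat = bundle$ksat, drainage = bundle$drainage,
                               wet_id_grid = del$wet_id_grid))
  truth <- bundle$truth
  truth$wet_id <- del$wet_id_grid$values[cbind(truth$anchor_row,
                                               truth$anchor_col)]
  truth$assigned_class <- records$class[match(truth$wet_id, records$wet_id)]
  bad <- which(is.na(truth$assigned_class) |
                 truth$assigned_class != truth$intended_class)
  mismatch <- sprintf("anchor (%d, %d): intended %s, got %s",
                      truth$anchor_row[bad], truth$anchor_col[bad],
                      truth$intended_class[bad], truth$assigned_class[bad])
  list(ok = length(bad) == 0 && nrow(truth) == nrow(records),
       records = records, truth = truth, mismatch = mismatch)
}
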