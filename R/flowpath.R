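# Flowpath tracing and the four-class connectivity assignment.
#
# Non-riparian wetlands are classified by the soils of the D8 flowpath from
# their pour point to the buffered streams: the minimum saturated hydraulic
# conductivity (Ksat) over the path separates permeable from impermeable
# flowpaths at 5.08 cm/h (the textural break between very fine sandy loams
# and sandy loams), and for permeable flowpaths the drainage class occurring
# over the greatest length of the path separates shallow from mid-depth
# subsurface flow. Ksat uses the minimum because the least permeable segment
# limits flow; drainage uses the length-majority because it characterises,
# rather than limits, the subsurface flow regime.

#' Connectivity class levels, highest connectivity first
#' @export
CONNECTIVITY_CLASSES <- c("Riparian", "NRShw", "NRMid", "NRDeep", "Unclassified")

#' Default Ksat permeability threshold (cm/h)
#'
#' Separates permeable from impermeable flowpath soils; 5.08 cm/h is the
#' NRCS textural threshold between very fine sandy loams and sandy loams.
#' @export
KSAT_THRESHOLD_DEFAULT <- 5.08

# NRCS drainage-class codes 1..7 and their binary grouping:
# 1 excessively drained, 2 somewhat excessively drained, 3 well drained,
# 4 moderately well drained  -> well drained
# 5 somewhat poorly drained, 6 poorly drained, 7 very poorly drained -> poor
.drainage_poor_codes <- c(5, 6, 7)
.drainage_well_codes <- c(1, 2, 3, 4)

#' Trace a D8 flowpath from a pour point to the buffered streams
#'
#' Walks the flow-direction grid downstream, crossing catchment boundaries
#' freely, and stops *before* stepping onto a stream cell: the path holds
#' land cells only, the pour point included (so the shortest successful path
#' has length 1). All failure modes are encoded in the terminal status,
#' never as errors.
#'
#' @param pour_point Integer `c(row, col)`.
#' @param fdr D8 flow-direction `raster_grid`.
#' @param streams Buffered-streams layer (provenance or boolean grid).
#' @param max_steps Step budget; default the grid cell count, which makes
#'   non-termination impossible.
#' @return List of class `flowpath`: `cells` (n x 2 matrix, pour point
#'   first), `terminal` (one of `"reached_stream"`, `"exited_grid"`,
#'   `"hit_nodata"`, `"loop_detected"`, `"max_steps"`), and `step_lengths`
#'   (distance of each inter-cell step: `cell_size` cardinal,
#'   `cell_size * sqrt(2)` diagonal).
#' @export
trace_flowpath <- function(pour_point, fdr, streams,
                           max_steps = length(fdr$values)) {
  stopifnot(max_steps >= 1)
  v <- fdr$values
  nr <- nrow(v); nc <- ncol(v)
  s <- stream_mask(streams)
  r <- pour_point[1]; c <- pour_point[2]
  if (r < 1 || r > nr || c < 1 || c > nc)
    stop(sprintf("pour point (%d, %d) outside grid", r, c))
  visited <- logical(nr * nc)
  rows <- integer(max_steps); cols <- integer(max_steps)
  rows[1] <- r; cols[1] <- c
  visited[.cell_index(r, c, nr)] <- TRUE
  len <- 1L
  terminal <- NULL
  repeat {
    k <- match(v[r, c], D8_CODES)
    if (is.na(k)) { terminal <- "hit_nodata"; break }
    tr <- r + .d8_drow[k]; tc <- c + .d8_dcol[k]
    if (tr < 1 || tr > nr || tc < 1 || tc > nc) { terminal <- "exited_grid"; break }
    if (s[tr, tc]) { terminal <- "reached_stream"; break }
    j <- .cell_index(tr, tc, nr)
    if (visited[j]) { terminal <- "loop_detected"; break }
    if (len >= max_steps) { terminal <- "max_steps"; break }
    len <- len + 1L
    rows[len] <- tr; cols[len] <- tc
    visited[j] <- TRUE
    r <- tr; c <- tc
  }
  cells <- cbind(row = rows[seq_len(len)], col = cols[seq_len(len)])
  steps <- if (len > 1) {
    diag_step <- abs(diff(cells[, 1])) == 1 & abs(diff(cells[, 2])) == 1
    ifelse(diag_step, sqrt(2), 1) * fdr$cell_size
  } else numeric(0)
  structure(list(cells = cells, terminal = terminal, step_lengths = steps),
            class = "flowpath")
}

#' Minimum Ksat along a flowpath
#'
#' The least permeable soil on the path limits flow, so the minimum over
#' path cells is used. Nodata cells are skipped; if no cell has data the
#' result is `NA` and the wetland falls to Unclassified.
#'
#' @param path A `flowpath` (or n x 2 cell matrix).
#' @param ksat `raster_grid` of saturated hydraulic conductivity, cm/h.
#' @return Minimum Ksat (cm/h) or `NA`.
#' @export
path_min_ksat <- function(path, ksat) {
  cells <- if (inherits(path, "flowpath")) path$cells else path
  vals <- ksat$values[cells]
  if (all(is.na(vals))) return(NA_real_)
  min(vals, na.rm = TRUE)
}

#' Length-majority drainage class along a flowpath
#'
#' Each path cell contributes the length of the step that reaches it (the
#' pour-point cell contributes one cell size); the binary drainage group —
#' poorly drained (NRCS somewhat poorly, poorly, very poorly drained) vs
#' well drained (excessively, somewhat excessively, well, moderately well
#' drained) — with the greater total length wins. An exact tie goes to
#' poorly drained, the conservative choice toward more frequent surface
#' connection. Nodata cells are skipped; no valid cell gives `NA`.
#'
#' @param path A `flowpath`.
#' @param drainage `raster_grid` of NRCS drainage-class codes 1..7.
#' @return `"poorly_drained"`, `"well_drained"`, or `NA`.
#' @export
path_majority_drainage <- function(path, drainage) {
  cells <- path$cells
  cs <- drainage$cell_size
  w <- c(cs, path$step_lengths)       # arrival-step length per cell
  vals <- drainage$values[cells]
  known <- !is.na(vals)
  if (!any(known)) return(NA_character_)
  bad <- known & !(vals %in% c(.drainage_poor_codes, .drainage_well_codes))
  if (any(bad))
    stop("unknown drainage-class code: ", vals[bad][1],
         " (expected NRCS codes 1-7)")
  poor_len <- sum(w[known & vals %in% .drainage_poor_codes])
  well_len <- sum(w[known & vals %in% .drainage_well_codes])
  if (poor_len >= well_len) "poorly_drained" else "well_drained"
}

#' Assign a connectivity class
#'
#' The decision flow: riparian adjacency is decided first and ignores soils
#' entirely; a failed flowpath or missing soil evidence gives Unclassified;
#' an impermeable flowpath (min Ksat below the threshold) gives NRDeep
#' without consulting drainage; a permeable flowpath is split by the
#' drainage majority into NRShw (poorly drained) or NRMid (well drained).
#' Ksat exactly at the threshold counts as permeable.
#'
#' @param adjacent Logical: pour point within one pixel of a stream.
#' @param min_ksat Minimum flowpath Ksat (cm/h) or `NA`.
#' @param drainage_majority `"poorly_drained"`, `"well_drained"`, or `NA`.
#' @param path_ok Logical: flowpath terminal was `"reached_stream"`.
#' @param threshold Ksat permeability threshold, cm/h.
#' @return One of [CONNECTIVITY_CLASSES].
#' @export
classify_wetland <- function(adjacent, min_ksat, drainage_majority, path_ok,
                             threshold = KSAT_THRESHOLD_DEFAULT) {
  stopifnot(threshold > 0)
  if (isTRUE(adjacent)) return("Riparian")
  if (!isTRUE(path_ok)) return("Unclassified")
  if (is.na(min_ksat)) return("Unclassified")
  if (min_ksat < threshold) return("NRDeep")
  if (is.na(drainage_majority)) return("Unclassified")
  if (drainage_majority == "poorly_drained") "NRShw" else "NRMid"
}

#' Classify every wetland unit in a landscape
#'
#' Runs the full per-unit procedure — riparian adjacency at the pour point,
#' flowpath tracing for non-adjacent units, soil aggregation, class
#' assignment — and returns one record per unit. Per-unit failures (no pour
#' point, failed trace, missing soils) degrade that unit to Unclassified and
#' never abort the batch.
#'
#' @param units List of wetland units from [delineate_wetlands()] (each with
#'   `pixels`, `pour_point`, ids and area).
#' @param layers Named list of aligned `raster_grid` layers: `fdr`,
#'   `streams` (provenance or boolean), `ksat`, `drainage`, and optionally
#'   `wet_id_grid` (for recording which downstream wetlands a path crosses).
#' @param threshold Ksat permeability threshold, cm/h.
#' @param max_steps Flowpath step budget; default grid cell count.
#' @return `data.frame` with one row per unit: `wet_id`, `patch_id`,
#'   `catchment_id`, `n_pixels`, `area_km2`, `pour_row`, `pour_col`,
#'   `adjacent`, `terminal`, `path_length_m`, `min_ksat`,
#'   `drainage_majority`, `class`, `downstream_wet_ids` (comma-separated, in
#'   path order).
#' @export
classify_all <- function(units, layers, threshold = KSAT_THRESHOLD_DEFAULT,
                         max_steps = NULL) {
  needed <- c("fdr", "streams", "ksat", "drainage")
  if (!all(needed %in% names(layers)))
    stop("layers must contain: ", paste(needed, collapse = ", "))
  check_alignment(layers[intersect(names(layers),
                                   c(needed, "wet_id_grid"))])
  if (is.null(max_steps)) max_steps <- length(layers$fdr$values)
  wid <- if (!is.null(layers$wet_id_grid)) layers$wet_id_grid$values else NULL

  n <- length(units)
  out <- data.frame(
    wet_id = integer(n), patch_id = integer(n), catchment_id = rep(NA_real_, n),
    n_pixels = integer(n), area_km2 = numeric(n),
    pour_row = rep(NA_integer_, n), pour_col = rep(NA_integer_, n),
    adjacent = rep(NA, n), terminal = rep(NA_character_, n),
    path_length_m = rep(NA_real_, n), min_ksat = rep(NA_real_, n),
    drainage_majority = rep(NA_character_, n),
    class = rep(NA_character_, n), downstream_wet_ids = rep("", n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    u <- units[[i]]
    out$wet_id[i] <- u$wet_id
    out$patch_id[i] <- u$patch_id
    out$catchment_id[i] <- if (is.null(u$catchment_id)) NA else u$catchment_id
    out$n_pixels[i] <- u$n_pixels
    out$area_km2[i] <- u$area_km2
    if (is.null(u$pour_point)) {
      out$terminal[i] <- "no_pour_point"
      out$class[i] <- "Unclassified"
      next
    }
    pp <- u$pour_point
    out$pour_row[i] <- pp[1]; out$pour_col[i] <- pp[2]
    if (is.na(out$catchment_id[i])) {
      # wetland pixels on nodata catchment: retained, routed to Unclassified
      out$terminal[i] <- "no_catchment"
      out$class[i] <- "Unclassified"
      next
    }
    adj <- is_riparian_adjacent(pp, layers$streams)
    out$adjacent[i] <- adj
    if (adj) {
      out$terminal[i] <- "not_traced"
      out$path_length_m[i] <- 0
      out$class[i] <- "Riparian"
      next
    }
    fp <- trace_flowpath(pp, layers$fdr, layers$streams, max_steps)
    out$terminal[i] <- fp$terminal
    out$path_length_m[i] <- sum(fp$step_lengths)
    if (!is.null(wid)) {
      touched <- wid[fp$cells]
      touched <- touched[touched != 0 & touched != u$wet_id]
      touched <- touched[!duplicated(touched)]
      out$downstream_wet_ids[i] <- paste(touched, collapse = ",")
    }
    path_ok <- fp$terminal == "reached_stream"
    cls <- tryCatch({
      mk <- path_min_ksat(fp, layers$ksat)
      dm <- path_majority_drainage(fp, layers$drainage)
      out$min_ksat[i] <- mk
      out$drainage_majority[i] <- dm
      classify_wetland(FALSE, mk, dm, path_ok, threshold)
    }, error = function(e) {
      # bad soil data degrades this unit only, never the batch
      out$terminal[i] <<- "soil_data_error"
      "Unclassified"
    })
    out$class[i] <- cls
  }
  out
}
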