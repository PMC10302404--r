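# Wetland delineation: land-cover mask -> contiguous patches -> subdivision
# by hydrologic catchment -> per-unit pour points and areas.
#
# A "wetland unit" is the working entity of the whole pipeline: the piece of
# a contiguous wetland patch falling inside one catchment. Units get dense
# ids (WetIds) in (patch_id, catchment_id) lexicographic order; ids are
# unique within a processing unit only.

#' Extract the wetland mask from a land-cover grid
#'
#' Wetlands are the woody (code 90) and emergent herbaceous (code 95)
#' land-cover classes combined; the distinction between the two codes is
#' deliberately discarded — it plays no role in connectivity.
#'
#' @param landcover Categorical `raster_grid`.
#' @param wetland_codes Codes treated as wetland. Default `c(90, 95)`.
#' @return Logical `raster_grid` (`layer_kind` `"wetland_mask"`).
#' @export
extract_wetland_mask <- function(landcover, wetland_codes = c(90, 95)) {
  m <- matrix(landcover$values %in% wetland_codes,
              nrow(landcover$values), ncol(landcover$values))
  raster_grid(m, cell_size = landcover$cell_size, origin = landcover$origin,
              nodata = landcover$nodata, layer_kind = "wetland_mask")
}

#' Subdivide wetland patches by catchment
#'
#' Splits each contiguous patch at catchment boundaries so every resulting
#' unit is hydrologically tied to a single stream segment's catchment. Pixels
#' whose catchment is nodata (e.g. at the grid edge) are retained as their
#' own flagged unit per patch and will classify as Unclassified.
#'
#' @param patch_labels Integer `raster_grid` from [label_patches()].
#' @param catchments Integer `raster_grid` of catchment ids (nodata allowed).
#' @return List of wetland units. Each unit is a list with `wet_id`,
#'   `patch_id`, `catchment_id` (`NA` if flagged), `pixels` (n x 2 matrix of
#'   row, col), `n_pixels` and `area_km2`. WetIds are dense from 1 in
#'   (patch_id, catchment_id) order, `NA` catchment sorting last within its
#'   patch.
#' @export
subdivide_by_catchment <- function(patch_labels, catchments) {
  check_alignment(patch_labels, catchments)
  pv <- patch_labels$values
  cv <- catchments$values
  idx <- which(pv > 0)
  if (length(idx) == 0) return(list())
  nr <- nrow(pv)
  patch <- pv[idx]
  catch <- cv[idx]
  # order keys: NA catchment last within each patch
  key <- order(patch, is.na(catch), catch)
  idx <- idx[key]; patch <- patch[key]; catch <- catch[key]
  tag <- paste(patch, ifelse(is.na(catch), "flagged", catch))
  grp <- cumsum(c(TRUE, tag[-1] != tag[-length(tag)]))
  cs <- patch_labels$cell_size
  units <- vector("list", max(grp))
  for (g in seq_len(max(grp))) {
    sel <- idx[grp == g]
    rows <- ((sel - 1L) %% nr) + 1L
    cols <- ((sel - 1L) %/% nr) + 1L
    units[[g]] <- list(
      wet_id = g,
      patch_id = patch[grp == g][1],
      catchment_id = catch[grp == g][1],
      pixels = cbind(row = rows, col = cols),
      n_pixels = length(sel),
      area_km2 = compute_area(length(sel), cs)
    )
  }
  units
}

#' Pour point of a wetland unit
#'
#' The unit's pixel with the highest flow-accumulation value — its hydrologic
#' outlet. Ties are broken by the smallest (row, col) in row-major order so
#' results are deterministic.
#'
#' @param pixels n x 2 matrix of (row, col) pixel coordinates, or a wetland
#'   unit list with a `pixels` element.
#' @param accumulation `raster_grid` of flow accumulation.
#' @return Integer `c(row, col)`, or `NULL` if every pixel is nodata in the
#'   accumulation grid (the unit is then routed to Unclassified).
#' @export
find_pour_point <- function(pixels, accumulation) {
  if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
  a <- accumulation$values[pixels]
  if (all(is.na(a))) return(NULL)
  mx <- max(a, na.rm = TRUE)
  cand <- which(!is.na(a) & a == mx)
  best <- cand[order(pixels[cand, 1], pixels[cand, 2])][1]
  unname(c(pixels[best, 1], pixels[best, 2]))
}

#' Pixel-count area in square kilometres
#'
#' @param n_pixels Positive pixel count.
#' @param cell_size Pixel edge in metres.
#' @return Area in km^2: `n_pixels * cell_size^2 / 1e6` (a 30 m pixel is
#'   900 m^2, i.e. 0.0009 km^2).
#' @export
compute_area <- function(n_pixels, cell_size) {
  if (n_pixels < 1) stop("a wetland unit must contain at least one pixel")
  if (cell_size <= 0) stop("cell_size must be positive")
  n_pixels * cell_size^2 / 1e6
}

#' Delineate wetland units from raster layers
#'
#' Full delineation: wetland mask, 8-connected patch labeling, subdivision by
#' catchment, pour-point detection and areas.
#'
#' @param landcover Categorical `raster_grid`.
#' @param catchments Catchment-id `raster_grid`.
#' @param accumulation Flow-accumulation `raster_grid`.
#' @param connectivity Patch connectivity, 8 (default) or 4.
#' @param wetland_codes Land-cover codes treated as wetland.
#' @return List with `units` (each unit augmented with `pour_point`, `NULL`
#'   when undefined) and `wet_id_grid` (`raster_grid` of unit labels, 0 where
#'   not wetland).
#' @export
delineate_wetlands <- function(landcover, catchments, accumulation,
                               connectivity = 8, wetland_codes = c(90, 95)) {
  check_alignment(landcover, catchments, accumulation)
  mask <- extract_wetland_mask(landcover, wetland_codes)
  patches <- label_patches(mask, connectivity)
  units <- subdivide_by_catchment(patches, catchments)
  lab <- matrix(0L, nrow(landcover$values), ncol(landcover$values))
  for (u in units) lab[u$pixels] <- u$wet_id
  units <- lapply(units, function(u) {
    u$pour_point <- find_pour_point(u$pixels, accumulation)
    u
  })
  list(units = units,
       wet_id_grid = raster_grid(lab, cell_size = landcover$cell_size,
                                 origin = landcover$origin,
                                 nodata = landcover$nodata,
                                 layer_kind = "wet_id"))
}
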