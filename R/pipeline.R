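# End-to-end orchestration: delineate -> streams -> classify -> summarize,
# from a config naming the input rasters. Per-wetland failures degrade to
# Unclassified; stage failures abort with the failing stage named.

#' Run the full classification pipeline
#'
#' Reads the aligned input rasters, delineates and classifies every wetland
#' unit, summarizes catchments (and watersheds when a topology table is
#' given), and writes `classified.csv`, `summaries.csv`, `stats.csv`, a
#' flowpath-cell raster `paths.asc` and a stage log. Deterministic for a
#' fixed config.
#'
#' @param config Named list (or path to a JSON file) with entries:
#'   `landcover`, `fdr`, `facc`, `catchments`, `streamlines`, `ksat`,
#'   `drainage` (paths to ASCII grids); optional `topology` (CSV of
#'   `from`,`to`), `domain_area_km2` (default: full grid area),
#'   `ksat_threshold` (default 5.08), `connectivity` (default 8), `out_dir`.
#' @return Invisibly, a list with `records`, `summaries`, `stats`, `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- c("landcover", "fdr", "facc", "catchments", "streamlines",
            "ksat", "drainage")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("config missing entries: ", paste(miss, collapse = ", "))
  thr <- if (!is.null(config$ksat_threshold)) config$ksat_threshold else KSAT_THRESHOLD_DEFAULT
  conn <- if (!is.null(config$connectivity)) config$connectivity else 8
  log <- character(0)
  say <- function(...) sprintf(...)

  stage <- "read"
  grids <- tryCatch(list(
    landcover = read_ascii_grid(config$landcover, "landcover"),
    fdr = read_ascii_grid(config$fdr, "flowdir"),
    facc = read_ascii_grid(config$facc, "accumulation"),
    catchments = read_ascii_grid(config$catchments, "catchment"),
    streamlines = read_ascii_grid(config$streamlines, "streamlines"),
    ksat = read_ascii_grid(config$ksat, "ksat"),
    drainage = read_ascii_grid(config$drainage, "drainage")
  ), error = function(e) stop("stage [read] failed: ", conditionMessage(e)))
  tryCatch(check_alignment(grids),
           error = function(e) stop("stage [align] failed: ", conditionMessage(e)))
  log <- c(log, say("read: %d layers, %d x %d cells at %g m",
                    length(grids), nrow(grids$landcover$values),
                    ncol(grids$landcover$values), grids$landcover$cell_size))

  stage <- "delineate"
  del <- tryCatch(
    delineate_wetlands(grids$landcover, grids$catchments, grids$facc,
                       connectivity = conn),
    error = function(e) stop("stage [delineate] failed: ", conditionMessage(e)))
  log <- c(log, say("delineate: %d wetland units", length(del$units)))

  stage <- "streams"
  streams <- tryCatch(
    build_buffered_streams(grids$landcover, grids$streamlines),
    error = function(e) stop("stage [streams] failed: ", conditionMessage(e)))
  log <- c(log, say("streams: %d buffered-stream cells", sum(stream_mask(streams))))

  stage <- "classify"
  records <- tryCatch(
    classify_all(del$units,
                 list(fdr = grids$fdr, streams = streams, ksat = grids$ksat,
                      drainage = grids$drainage, wet_id_grid = del$wet_id_grid),
                 threshold = thr),
    error = function(e) stop("stage [classify] failed: ", conditionMessage(e)))
  counts <- table(factor(records$class, levels = CONNECTIVITY_CLASSES))
  log <- c(log, say("classify: %s",
                    paste(names(counts), counts, sep = "=", collapse = " ")))

  stage <- "summarize"
  cell_area <- grids$landcover$cell_size^2 / 1e6
  cv <- grids$catchments$values
  ctab <- table(cv[!is.na(cv)])
  catchment_areas <- data.frame(catchment_id = as.numeric(names(ctab)),
                                area_km2 = as.numeric(ctab) * cell_area)
  summaries <- tryCatch({
    s <- local_percentages(records, catchment_areas)
    if (!is.null(config$topology)) {
      topo <- utils::read.csv(config$topology)
      s <- accumulate_watershed(s, topo)
    }
    s
  }, error = function(e) stop("stage [summarize] failed: ", conditionMessage(e)))
  domain <- if (!is.null(config$domain_area_km2)) config$domain_area_km2
            else length(grids$landcover$values) * cell_area
  stats <- summary_statistics(records, domain)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(config$out_dir, "classified.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE)
    paths <- .flowpath_raster(records, del, grids, streams, thr)
    write_ascii_grid(paths, file.path(config$out_dir, "paths.asc"))
    writeLines(log, file.path(config$out_dir, "pipeline.log"))
  }
  invisible(list(records = records, summaries = summaries, stats = stats,
                 log = log))
}

# raster marking every traced flowpath cell with its wetland's id
.flowpath_raster <- function(records, del, grids, streams, thr) {
  m <- matrix(0, nrow(grids$fdr$values), ncol(grids$fdr$values))
  for (i in seq_len(nrow(records))) {
    if (is.na(records$pour_row[i]) || isTRUE(records$adjacent[i])) next
    if (records$terminal[i] %in% c("no_pour_point", "no_catchment", "not_traced")) next
    fp <- trace_flowpath(c(records$pour_row[i], records$pour_col[i]),
                         grids$fdr, streams)
    m[fp$cells] <- records$wet_id[i]
  }
  raster_grid(m, cell_size = grids$fdr$cell_size, origin = grids$fdr$origin,
              nodata = grids$fdr$nodata, layer_kind = "flowpaths")
}

#' Write a scenario bundle to a directory
#'
#' Writes every grid as an ASCII raster plus `truth.csv` and `topology.csv`,
#' and a ready-to-use pipeline config `run.json`.
#'
#' @param bundle A scenario bundle from [generate_scenario()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the config list.
#' @export
write_scenario <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_ascii_grid(bundle$landcover, p("landcover.asc"))
  write_ascii_grid(bundle$fdr, p("fdr.asc"))
  write_ascii_grid(bundle$accumulation, p("facc.asc"))
  write_ascii_grid(bundle$streamlines, p("streamlines.asc"))
  write_ascii_grid(bundle$catchments, p("catchments.asc"))
  write_ascii_grid(bundle$ksat, p("ksat.asc"))
  write_ascii_grid(bundle$drainage, p("drainage.asc"))
  utils::write.csv(bundle$truth, p("truth.csv"), row.names = FALSE)
  utils::write.csv(bundle$topology, p("topology.csv"), row.names = FALSE)
  config <- list(landcover = p("landcover.asc"), fdr = p("fdr.asc"),
                 facc = p("facc.asc"), catchments = p("catchments.asc"),
                 streamlines = p("streamlines.asc"), ksat = p("ksat.asc"),
                 drainage = p("drainage.asc"),
                 topology = p("topology.csv"))
  jsonlite::write_json(config, p("run.json"), auto_unbox = TRUE)
  invisible(config)
}

#' Read a scenario bundle from a directory written by [write_scenario()]
#'
#' @param dir Directory path.
#' @return A scenario bundle (without the DEM, which is not an input layer).
#' @export
read_scenario <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    landcover = read_ascii_grid(p("landcover.asc"), "landcover"),
    fdr = read_ascii_grid(p("fdr.asc"), "flowdir"),
    accumulation = read_ascii_grid(p("facc.asc"), "accumulation"),
    streamlines = read_ascii_grid(p("streamlines.asc"), "streamlines"),
    catchments = read_ascii_grid(p("catchments.asc"), "catchment"),
    ksat = read_ascii_grid(p("ksat.asc"), "ksat"),
    drainage = read_ascii_grid(p("drainage.asc"), "drainage"),
    truth = utils::read.csv(p("truth.csv"), stringsAsFactors = FALSE),
    topology = utils::read.csv(p("topology.csv"))
  )
}
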