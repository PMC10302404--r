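# Catchment and watershed summaries of classified wetlands: percent of area
# per class (local and accumulated upstream), dominant class, and
# per-class summary statistics.

#' Local per-class wetland percentages by catchment
#'
#' For each catchment: per-class wetland area as a percent of catchment
#' area, plus the dominant class by area.
#'
#' @param records Wetland record `data.frame` from [classify_all()] (needs
#'   `catchment_id`, `class`, `area_km2`).
#' @param catchment_areas `data.frame` with `catchment_id` and `area_km2`.
#'   Every catchment referenced by a record must be present.
#' @return `data.frame` with `catchment_id`, `local_area_km2`, one
#'   `pct_<class>` column per class (0-100), `wetland_area_km2` and
#'   `dominant_class` (`NA` if no wetlands).
#' @export
local_percentages <- function(records, catchment_areas) {
  recs <- records[!is.na(records$catchment_id), , drop = FALSE]
  miss <- setdiff(unique(recs$catchment_id), catchment_areas$catchment_id)
  if (length(miss) > 0)
    stop("catchment(s) missing from areas table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- data.frame(catchment_id = catchment_areas$catchment_id,
                    local_area_km2 = catchment_areas$area_km2)
  class_area <- matrix(0, nrow(out), length(CONNECTIVITY_CLASSES),
                       dimnames = list(NULL, CONNECTIVITY_CLASSES))
  if (nrow(recs) > 0) {
    agg <- stats::aggregate(area_km2 ~ catchment_id + class, data = recs, sum)
    ri <- match(agg$catchment_id, out$catchment_id)
    ci <- match(agg$class, CONNECTIVITY_CLASSES)
    class_area[cbind(ri, ci)] <- agg$area_km2
  }
  for (cl in CONNECTIVITY_CLASSES) {
    out[[paste0("area_", cl)]] <- class_area[, cl]
    out[[paste0("pct_", cl)]] <- 100 * class_area[, cl] / out$local_area_km2
  }
  out$wetland_area_km2 <- rowSums(class_area)
  out$dominant_class <- apply(class_area, 1, dominant_class)
  out
}

#' Dominant connectivity class of a catchment
#'
#' The class with the greatest local wetland area. Ties go to the class with
#' higher connectivity (Riparian > NRShw > NRMid > NRDeep > Unclassified);
#' `NA` when there is no wetland area at all.
#'
#' @param class_areas Named numeric vector of per-class areas (names from
#'   [CONNECTIVITY_CLASSES]; missing classes count as 0).
#' @return Class name or `NA`.
#' @export
dominant_class <- function(class_areas) {
  a <- stats::setNames(rep(0, length(CONNECTIVITY_CLASSES)), CONNECTIVITY_CLASSES)
  a[names(class_areas)] <- class_areas
  if (all(a == 0)) return(NA_character_)
  # which.max returns the first maximum; order is decreasing connectivity
  CONNECTIVITY_CLASSES[which.max(a)]
}

#' Accumulate per-class percentages over watersheds
#'
#' The watershed of a catchment is the catchment plus everything upstream.
#' Wetland and land areas are summed over the watershed *before* dividing —
#' percentages are never averaged, only area ratios are formed — so the
#' accumulated percent is well defined and area-conservative.
#'
#' @param summaries Output of [local_percentages()].
#' @param topology `data.frame` with `from` and `to` catchment ids (flow goes
#'   from -> to). Must be acyclic; ids must exist in `summaries`.
#' @return `summaries` with added `watershed_area_km2` and one
#'   `wpct_<class>` column per class.
#' @export
accumulate_watershed <- function(summaries, topology) {
  ids <- summaries$catchment_id
  n <- length(ids)
  if (nrow(topology) > 0) {
    unknown <- setdiff(c(topology$from, topology$to), ids)
    if (length(unknown) > 0)
      stop("topology references unknown catchment(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  from <- match(topology$from, ids)
  to <- match(topology$to, ids)
  # topological order by Kahn's algorithm; leftovers indicate a cycle
  indeg <- tabulate(to, nbins = n)
  order_out <- integer(n)
  queue <- which(indeg == 0L)
  qn <- length(queue)
  pos <- 0L
  kids <- split(to, from)
  while (pos < qn) {
    pos <- pos + 1L
    i <- queue[pos]
    order_out[pos] <- i
    for (j in kids[[as.character(i)]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { qn <- qn + 1L; queue[qn] <- j }
    }
  }
  if (pos < n) stop("cycle detected in catchment topology")
  acls <- paste0("area_", CONNECTIVITY_CLASSES)
  warea <- summaries$local_area_km2
  wcls <- as.matrix(summaries[, acls])
  for (p in seq_len(pos)) {
    i <- order_out[p]
    e <- which(from == i)
    for (j in to[e]) {
      warea[j] <- warea[j] + warea[i]
      wcls[j, ] <- wcls[j, ] + wcls[i, ]
    }
  }
  summaries$watershed_area_km2 <- warea
  for (k in seq_along(CONNECTIVITY_CLASSES))
    summaries[[paste0("wpct_", CONNECTIVITY_CLASSES[k])]] <-
      100 * wcls[, k] / warea
  summaries
}

#' Per-class wetland summary statistics
#'
#' Counts, total area, mean area and percent of domain per class, plus an
#' all-classes total row.
#'
#' @param records Wetland record `data.frame` (needs `class` and
#'   `area_km2`), or `NULL` when `counts`/`areas` are given directly.
#' @param domain_area_km2 Total land area of the analysis domain (> 0).
#' @param counts,areas Optional named vectors (names from
#'   [CONNECTIVITY_CLASSES]) giving per-class wetland counts and total areas
#'   directly, e.g. when summarising an already-aggregated table.
#' @return `data.frame` with rows per class plus `"Total"`: `class`,
#'   `n_wetlands`, `total_area_km2`, `mean_area_km2` (`NA` when n = 0),
#'   `pct_of_domain`.
#' @export
summary_statistics <- function(records = NULL, domain_area_km2,
                               counts = NULL, areas = NULL) {
  if (domain_area_km2 <= 0) stop("domain_area_km2 must be positive")
  if (is.null(counts)) {
    counts <- stats::setNames(rep(0, length(CONNECTIVITY_CLASSES)),
                              CONNECTIVITY_CLASSES)
    areas <- counts
    if (!is.null(records) && nrow(records) > 0) {
      tb <- table(factor(records$class, levels = CONNECTIVITY_CLASSES))
      counts[names(tb)] <- as.numeric(tb)
      ag <- tapply(records$area_km2,
                   factor(records$class, levels = CONNECTIVITY_CLASSES), sum)
      areas[!is.na(ag)] <- ag[!is.na(ag)]
    }
  } else {
    full <- stats::setNames(rep(0, length(CONNECTIVITY_CLASSES)),
                            CONNECTIVITY_CLASSES)
    full[names(counts)] <- counts; counts <- full
    full[] <- 0; full[names(areas)] <- areas; areas <- full
  }
  cls <- c(CONNECTIVITY_CLASSES, "Total")
  n <- c(counts, sum(counts))
  a <- c(areas, sum(areas))
  data.frame(
    class = cls,
    n_wetlands = unname(n),
    total_area_km2 = unname(a),
    mean_area_km2 = unname(ifelse(n > 0, a / n, NA_real_)),
    pct_of_domain = unname(100 * a / domain_area_km2),
    stringsAsFactors = FALSE
  )
}
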