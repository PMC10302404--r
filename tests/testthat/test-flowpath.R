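test_that("a straight flowpath stops before the stream and keeps land cells only", {
  v <- matrix(1, 5, 8)               # all east
  s <- matrix(FALSE, 5, 8); s[, 7] <- TRUE
  fp <- trace_flowpath(c(3, 4), rg(v), rg(s))
  expect_equal(fp$terminal, "reached_stream")
  expect_equal(fp$cells, cbind(row = c(3, 3, 3), col = c(4, 5, 6)))
  expect_equal(fp$step_lengths, c(30, 30))
  expect_false(any(s[fp$cells]))
})

test_that("flowpath failure modes are encoded in the terminal", {
  v <- matrix(1, 3, 3); v[2, 2] <- 1; v[2, 3] <- 16   # E then W: 2-cycle
  fp <- trace_flowpath(c(2, 2), rg(v), rg(matrix(FALSE, 3, 3)))
  expect_equal(fp$terminal, "loop_detected")
  v <- matrix(1, 3, 3)
  fp <- trace_flowpath(c(2, 2), rg(v), rg(matrix(FALSE, 3, 3)))
  expect_equal(fp$terminal, "exited_grid")
  v[2, 3] <- NA
  fp <- trace_flowpath(c(2, 1), rg(v), rg(matrix(FALSE, 3, 3)))
  expect_equal(fp$terminal, "hit_nodata")
  expect_equal(nrow(fp$cells), 3)   # the nodata cell ends the path, inside it
  fp <- trace_flowpath(c(2, 1), rg(matrix(1, 3, 9)), rg(matrix(FALSE, 3, 9)),
                       max_steps = 4)
  expect_equal(fp$terminal, "max_steps")
  expect_equal(nrow(fp$cells), 4)
})

test_that("flowpaths match the stepwise oracle on random acyclic grids", {
  set.seed(41)
  for (i in 1:60) {
    v <- random_acyclic_fdr(10, 10, p_nodata = 0.08)
    s <- matrix(runif(100) < 0.1, 10, 10)
    start <- c(sample(10, 1), sample(10, 1))
    if (s[start[1], start[2]]) next
    fp <- trace_flowpath(start, rg(v), rg(s))
    w <- oracle_walk(v, start[1], start[2], stream = s)
    expect_equal(fp$terminal, w$reason)
    expect_equal(unname(fp$cells), unname(w$cells))
  }
})

test_that("minimum Ksat rules the path and skips nodata", {
  v <- matrix(1, 1, 5)
  s <- matrix(FALSE, 1, 5); s[1, 5] <- TRUE
  fp <- trace_flowpath(c(1, 1), rg(v), rg(s))   # cells 1..4
  k <- rg(matrix(c(10, 6, 3, 8, 99), 1, 5), layer_kind = "ksat")
  expect_equal(path_min_ksat(fp, k), 3)
  k$values[1, 3] <- NA
  expect_equal(path_min_ksat(fp, k), 6)
  k$values[] <- NA
  expect_true(is.na(path_min_ksat(fp, k)))
})

test_that("drainage majority is length-weighted with the documented tie rule", {
  v <- matrix(1, 1, 5)
  s <- matrix(FALSE, 1, 5); s[1, 4] <- TRUE
  fp <- trace_flowpath(c(1, 1), rg(v), rg(s))   # 3 cardinal cells
  d <- rg(matrix(c(6, 6, 3, 1, 1), 1, 5), layer_kind = "drainage")
  expect_equal(path_majority_drainage(fp, d), "poorly_drained")  # 2/3 poor
  # diagonal step outweighs a cardinal one: sqrt(2)*30 of well vs 30 of poor
  v2 <- matrix(NA_real_, 3, 3); v2[1, 1] <- 2                    # SE step
  s2 <- matrix(FALSE, 3, 3); s2[3, 3] <- TRUE
  v2[2, 2] <- 2
  fp2 <- trace_flowpath(c(1, 1), rg(v2), rg(s2))
  expect_equal(fp2$step_lengths, 30 * sqrt(2))
  d2 <- rg(matrix(c(6, NA, NA, NA, 3, NA, NA, NA, NA), 3, 3, byrow = TRUE))
  expect_equal(path_majority_drainage(fp2, d2), "well_drained")
  # hand check: well length 42.43 > poor length 30
  # exact tie -> poorly drained
  d3 <- rg(matrix(c(6, NA, NA, NA, NA, NA, NA, NA, NA), 3, 3, byrow = TRUE))
  d3$values[2, 2] <- 3
  fp3 <- trace_flowpath(c(1, 1), rg(matrix(c(4, rep(NA, 8)), 3, 3)),
                        rg({m <- matrix(FALSE, 3, 3); m[3, 1] <- TRUE; m}))
  expect_equal(fp3$step_lengths, 30)          # cardinal S step
  d4 <- rg(matrix(NA_real_, 3, 3)); d4$values[1, 1] <- 6; d4$values[2, 1] <- 3
  expect_equal(path_majority_drainage(fp3, d4), "poorly_drained")
  # unknown code is a data error naming the code
  d5 <- rg(matrix(9, 3, 3))
  expect_error(path_majority_drainage(fp3, d5), "9")
  # all nodata -> undefined
  expect_true(is.na(path_majority_drainage(fp3, rg(matrix(NA_real_, 3, 3)))))
})

test_that("the classifier reproduces the full decision flow, no gap", {
  thr <- KSAT_THRESHOLD_DEFAULT
  ks <- c(below = 3, equal = thr, above = 10, undefined = NA)
  dr <- c(poor = "poorly_drained", well = "well_drained", undefined = NA)
  # hand-enumerated expectation encoding the decision flow chart:
  # adjacency first; then path failure/missing soils; then Ksat; then drainage
  expected <- function(adj, k, d, ok) {
    if (adj) return("Riparian")
    if (!ok) return("Unclassified")
    if (is.na(k)) return("Unclassified")
    if (k < thr) return("NRDeep")
    if (is.na(d)) return("Unclassified")
    if (d == "poorly_drained") return("NRShw")
    "NRMid"
  }
  n <- 0
  for (adj in c(TRUE, FALSE)) for (k in ks) for (d in dr) for (ok in c(TRUE, FALSE)) {
    expect_equal(classify_wetland(adj, k, d, ok), expected(adj, k, d, ok),
                 info = sprintf("adj=%s k=%s d=%s ok=%s", adj, k, d, ok))
    n <- n + 1
  }
  expect_equal(n, 2 * 4 * 3 * 2)   # every combination visited
  # boundary: exactly at threshold is permeable
  expect_equal(classify_wetland(FALSE, thr, "well_drained", TRUE), "NRMid")
  expect_equal(classify_wetland(FALSE, thr, "poorly_drained", TRUE), "NRShw")
  # adjacency ignores soils entirely
  expect_equal(classify_wetland(TRUE, 1.0, "poorly_drained", FALSE), "Riparian")
})

test_that("raising the Ksat threshold only moves wetlands toward NRDeep", {
  set.seed(51)
  b <- generate_scenario(seed = 99)
  streams <- build_buffered_streams(b$landcover, b$streamlines)
  del <- delineate_wetlands(b$landcover, b$catchments, b$accumulation)
  layers <- list(fdr = b$fdr, streams = streams, ksat = b$ksat,
                 drainage = b$drainage, wet_id_grid = del$wet_id_grid)
  rank <- c(Riparian = 0, NRShw = 1, NRMid = 1, NRDeep = 2, Unclassified = 0)
  prev <- classify_all(del$units, layers, threshold = 1)$class
  for (thr in c(3, 5.08, 9, 15)) {
    cur <- classify_all(del$units, layers, threshold = thr)$class
    nonrip <- prev %in% c("NRShw", "NRMid", "NRDeep")
    expect_true(all(rank[cur[nonrip]] >= rank[prev[nonrip]]))
    # riparian and unclassified assignments are threshold-invariant
    expect_equal(cur[!nonrip], prev[!nonrip])
    prev <- cur
  }
})

test_that("riparian assignment is invariant to soil-grid permutations", {
  b <- generate_scenario(seed = 123)
  streams <- build_buffered_streams(b$landcover, b$streamlines)
  del <- delineate_wetlands(b$landcover, b$catchments, b$accumulation)
  base <- classify_all(del$units, list(fdr = b$fdr, streams = streams,
                                       ksat = b$ksat, drainage = b$drainage))
  set.seed(61)
  for (i in 1:5) {
    k2 <- b$ksat; k2$values[] <- sample(k2$values)
    d2 <- b$drainage; d2$values[] <- sample(d2$values)
    scr <- classify_all(del$units, list(fdr = b$fdr, streams = streams,
                                        ksat = k2, drainage = d2))
    rip <- base$class == "Riparian"
    expect_equal(scr$class[rip], base$class[rip])
  }
})

test_that("classify_all handles empty input and per-unit failures", {
  layers <- list(fdr = rg(matrix(1, 3, 3)), streams = rg(matrix(FALSE, 3, 3)),
                 ksat = rg(matrix(10, 3, 3)), drainage = rg(matrix(3, 3, 3)))
  expect_equal(nrow(classify_all(list(), layers)), 0)
  # unit whose path exits the grid (no stream anywhere)
  unit <- list(wet_id = 1, patch_id = 1, catchment_id = 1,
               pixels = cbind(row = 2, col = 1), n_pixels = 1,
               area_km2 = 0.0009, pour_point = c(2, 1))
  rec <- classify_all(list(unit), layers)
  expect_equal(rec$class, "Unclassified")
  expect_equal(rec$terminal, "exited_grid")
  # nodata catchment -> Unclassified without tracing
  unit$catchment_id <- NA
  rec <- classify_all(list(unit), layers)
  expect_equal(rec$class, "Unclassified")
  expect_equal(rec$terminal, "no_catchment")
  # missing pour point
  unit$catchment_id <- 1; unit$pour_point <- NULL
  rec <- classify_all(list(unit), layers)
  expect_equal(rec$terminal, "no_pour_point")
})

test_that("flowpaths cross catchment boundaries until they meet a stream", {
  # catchment 1 (cols 1-3) has no stream; the path continues into catchment 2
  v <- matrix(1, 3, 6)
  s <- matrix(FALSE, 3, 6); s[, 6] <- TRUE
  cat <- matrix(1, 3, 6); cat[, 4:6] <- 2
  fp <- trace_flowpath(c(2, 2), rg(v), rg(s))
  expect_equal(fp$terminal, "reached_stream")
  expect_equal(sort(unique(cat[fp$cells])), c(1, 2))
})
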