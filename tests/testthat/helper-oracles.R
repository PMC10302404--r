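# Independent brute-force oracles used to check the package's raster
# algorithms. Deliberately written as naive per-cell walks/searches, not
# sharing code paths with the implementation.

# D8 code -> (drow, dcol), duplicated here on purpose
ORACLE_D8 <- list(`1` = c(0, 1), `2` = c(1, 1), `4` = c(1, 0), `8` = c(1, -1),
                  `16` = c(0, -1), `32` = c(-1, -1), `64` = c(-1, 0),
                  `128` = c(-1, 1))

# one downstream step; NA vector if none
oracle_step <- function(v, r, c) {
  off <- ORACLE_D8[[as.character(v[r, c])]]
  if (is.null(off)) return(NULL)
  tr <- r + off[1]; tc <- c + off[2]
  if (tr < 1 || tr > nrow(v) || tc < 1 || tc > ncol(v)) return(NULL)
  c(tr, tc)
}

# full downstream walk from (r, c); returns list(cells = matrix, reason)
oracle_walk <- function(v, r, c, stream = NULL, max_steps = 1e6) {
  cells <- matrix(c(r, c), 1, 2)
  seen <- paste(r, c)
  repeat {
    cur <- cells[nrow(cells), ]
    if (is.null(ORACLE_D8[[as.character(v[cur[1], cur[2]])]]))
      return(list(cells = cells, reason = "hit_nodata"))
    nxt <- oracle_step(v, cur[1], cur[2])
    if (is.null(nxt)) return(list(cells = cells, reason = "exited_grid"))
    if (!is.null(stream) && stream[nxt[1], nxt[2]])
      return(list(cells = cells, reason = "reached_stream"))
    key <- paste(nxt[1], nxt[2])
    if (key %in% seen) return(list(cells = cells, reason = "loop_detected"))
    if (nrow(cells) >= max_steps) return(list(cells = cells, reason = "max_steps"))
    cells <- rbind(cells, nxt)
    seen <- c(seen, key)
  }
}

# accumulation by counting, for every cell, how many cells' walks pass
# through it (graph-reachability: ancestors + self)
oracle_accumulation <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    valid[r, c] <- !is.null(ORACLE_D8[[as.character(v[r, c])]])
  acc[valid] <- 0
  for (r in 1:nr) for (c in 1:nc) {
    if (!valid[r, c]) next
    w <- oracle_walk(v, r, c)
    for (i in seq_len(nrow(w$cells))) {
      cr <- w$cells[i, 1]; cc <- w$cells[i, 2]
      if (valid[cr, cc]) acc[cr, cc] <- acc[cr, cc] + 1
      else break   # walk drains onto nodata: stops contributing there
    }
  }
  acc
}

# flood-fill labeling oracle via repeated masked dilation
oracle_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8) ORACLE_D8 else ORACLE_D8[c("1", "4", "16", "64")]
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in 1:nr) for (c in 1:nc) {
    if (!isTRUE(mask[r, c]) || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    grow <- matrix(c(r, c), 1, 2)
    lab[r, c] <- nxt
    while (nrow(grow) > 0) {
      cur <- grow[1, , drop = FALSE]
      grow <- grow[-1, , drop = FALSE]
      for (o in offs) {
        tr <- cur[1] + o[1]; tc <- cur[2] + o[2]
        if (tr < 1 || tr > nr || tc < 1 || tc > nc) next
        if (isTRUE(mask[tr, tc]) && lab[tr, tc] == 0L) {
          lab[tr, tc] <- nxt
          grow <- rbind(grow, c(tr, tc))
        }
      }
    }
  }
  lab
}

# labelings agree up to renumbering
same_partition <- function(a, b) {
  if (!all((a == 0) == (b == 0))) return(FALSE)
  ka <- a[a != 0]; kb <- b[b != 0]
  length(unique(paste(ka, kb))) == length(unique(ka)) &&
    length(unique(paste(ka, kb))) == length(unique(kb))
}

# random acyclic D8 grid: cells ranked by a random permutation, each cell
# points at a random strictly-lower-ranked neighbor (nodata if none)
random_acyclic_fdr <- function(nr, nc, p_nodata = 0.1) {
  rank <- matrix(sample(nr * nc), nr, nc)
  v <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (runif(1) < p_nodata) next
    cand <- c()
    for (code in names(ORACLE_D8)) {
      o <- ORACLE_D8[[code]]
      tr <- r + o[1]; tc <- c + o[2]
      if (tr >= 1 && tr <= nr && tc >= 1 && tc <= nc && rank[tr, tc] < rank[r, c])
        cand <- c(cand, as.numeric(code))
    }
    if (length(cand) > 0) v[r, c] <- cand[sample.int(length(cand), 1)]
  }
  v
}

# brute-force Chebyshev distance from a cell to the nearest TRUE cell
oracle_chebyshev <- function(cell, mask) {
  best <- Inf
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (isTRUE(mask[r, c]))
      best <- min(best, max(abs(r - cell[1]), abs(c - cell[2])))
  best
}

# watershed subtree sums by recursion over a parent ("to") map
oracle_watershed_area <- function(id, local, topology) {
  kids <- topology$from[topology$to == id]
  local[[as.character(id)]] + sum(vapply(kids, function(k)
    oracle_watershed_area(k, local, topology), numeric(1)))
}

# shorthand grid constructor for tests
rg <- function(m, ...) raster_grid(m, ...)
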