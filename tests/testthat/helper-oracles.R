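# Independent brute-force oracles used across the suite. These deliberately
# reimplement the operations in the plainest possible way (array scans,
# exhaustive enumeration) and must stay decoupled from the package internals.

# naive O(V^2) array-scan Dijkstra on the conductance lattice; same edge
# rule (distance / mean conductance, sqrt(2) diagonals, 0 = barrier)
naive_dijkstra <- function(cond, src, connectivity = 8, cellsize = 100) {
  nr <- nrow(cond); nc <- ncol(cond)
  n <- nr * nc
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[src] <- 0
  offs <- list(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                         c(1, -1, sqrt(2)), c(1, 1, sqrt(2))))
  }
  cond_rm <- as.vector(t(cond))
  if (cond_rm[src] <= 0) stop("source on barrier")
  for (iter in seq_len(n)) {
    u <- NA
    best <- Inf
    for (i in seq_len(n)) {
      if (!done[i] && dist[i] < best) {
        best <- dist[i]; u <- i
      }
    }
    if (is.na(u)) break
    done[u] <- TRUE
    ur <- (u - 1) %/% nc + 1
    uc <- (u - 1) %% nc + 1
    for (o in offs) {
      vr <- ur + o[1]; vc <- uc + o[2]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vr - 1) * nc + vc
      if (cond_rm[v] <= 0 || cond_rm[u] <= 0) next
      w <- o[3] * cellsize / ((cond_rm[u] + cond_rm[v]) / 2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# exhaustive minimum cost over all simple paths (tiny grids only)
enumerate_min_cost <- function(cond, src, dst, connectivity = 8,
                               cellsize = 100) {
  nr <- nrow(cond); nc <- ncol(cond)
  cond_rm <- as.vector(t(cond))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  if (connectivity == 4) offs <- offs[abs(offs$dr) + abs(offs$dc) == 1, ]
  best <- Inf
  visited <- rep(FALSE, nr * nc)
  recurse <- function(u, cost) {
    if (cost >= best) return()
    if (u == dst) {
      best <<- cost
      return()
    }
    visited[u] <<- TRUE
    ur <- (u - 1) %/% nc + 1
    uc <- (u - 1) %% nc + 1
    for (m in seq_len(nrow(offs))) {
      vr <- ur + offs$dr[m]; vc <- uc + offs$dc[m]
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vr - 1) * nc + vc
      if (visited[v] || cond_rm[v] <= 0) next
      d <- cellsize * sqrt(offs$dr[m]^2 + offs$dc[m]^2)
      recurse(v, cost + d / ((cond_rm[u] + cond_rm[v]) / 2))
    }
    visited[u] <<- FALSE
  }
  if (cond_rm[src] > 0) recurse(src, 0)
  best
}

# brute-force Holm step-down: sort, multiply by m - i + 1, cummax, cap at 1
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- pmin(1, cummax(p[ord] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# brute-force per-block modal class with lowest-code tie-break
brute_block_mode <- function(m, f) {
  nrC <- nrow(m) %/% f; ncC <- ncol(m) %/% f
  out <- matrix(NA_real_, nrC, ncC)
  for (R in seq_len(nrC)) {
    for (C in seq_len(ncC)) {
      block <- as.vector(m[((R - 1) * f + 1):(R * f),
                           ((C - 1) * f + 1):(C * f)])
      tab <- table(block)
      codes <- as.numeric(names(tab))
      out[R, C] <- min(codes[tab == max(tab)])
    }
  }
  out
}

# a tiny hand-built landscape: flat lowland west, highland east, all-forest
# column strip in the highlands, aligned 100 m grid starting at the origin
tiny_landscape <- function(nr = 40, nc = 60, cellsize = 100) {
  elev <- matrix(rep(seq(0, 2000, length.out = nc), each = nr), nr, nc)
  lc <- matrix(40L, nr, nc)
  lc[, elev[1, ] >= 1500] <- 10L
  integ <- matrix(0, nr, nc)
  integ[lc == 10L] <- 9
  biom <- matrix(0, nr, nc)
  biom[lc == 10L] <- 60
  list(dem = grid_raster(elev, cellsize = cellsize),
       landcover = grid_raster(lc, cellsize = cellsize),
       integrity = grid_raster(integ, cellsize = cellsize),
       biomass = grid_raster(biom, cellsize = cellsize))
}

# axis-aligned rectangle ring
rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
}

# minimal reserve-table row builder
reserve_row <- function(id, geometry, status = "designated",
                        designation = "National Park", marine = FALSE,
                        reported_area = polygon_area(geometry) / 1e6,
                        name = sprintf("Reserve %03d", id)) {
  out <- data.frame(id = id, name = name, status = status,
                    designation = designation, marine = marine,
                    reported_area = reported_area, stringsAsFactors = FALSE)
  out$geometry <- list(geometry)
  out
}
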