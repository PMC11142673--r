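#' Lattice graph over a conductance surface
#'
#' Represents the weighted 4- or 8-connected lattice implied by a
#' conductance raster. The edge weight between neighbor cells i and j is
#' `d(i, j) / ((c_i + c_j) / 2)` with `d` the center-to-center distance
#' (cell size for rook moves, cell size times sqrt(2) for diagonal moves),
#' i.e. distance divided by the arithmetic-mean conductance. Cells with
#' conductance 0 are hard barriers and carry no edges. Edges are never
#' materialized for large grids; [lattice_edges()] enumerates them for
#' small fixtures and oracles.
#'
#' @param surface a conductance `grid_raster` (values `>= 0`).
#' @param connectivity 8 (default, diagonal moves allowed) or 4.
#' @return An object of class `lattice_graph`.
#' @export
build_graph <- function(surface, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  v <- surface$values
  if (any(is.na(v))) stop("conductance surface contains NA cells")
  if (any(v < 0)) stop("conductance must be non-negative")
  if (all(v <= 0)) warning("conductance surface is all zero: empty graph")
  structure(list(cond = v, cond_rm = as.vector(t(v)),
                 nrow = nrow(v), ncol = ncol(v),
                 cellsize = surface$cellsize,
                 xmin = surface$xmin, ymin = surface$ymin,
                 connectivity = as.integer(connectivity)),
            class = "lattice_graph")
}

#' Enumerate lattice edges (small grids)
#'
#' @param graph a [build_graph()] result.
#' @return A data.frame with 1-based row-major cell indices `from`, `to`
#'   (`from < to`) and the symmetric edge `weight`.
#' @export
lattice_edges <- function(graph) {
  nr <- graph$nrow; nc <- graph$ncol
  cond <- graph$cond_rm
  offs <- if (graph$connectivity == 8) {
    list(c(0, 1, graph$cellsize), c(1, 0, graph$cellsize),
         c(1, 1, graph$cellsize * sqrt(2)), c(1, -1, graph$cellsize * sqrt(2)))
  } else {
    list(c(0, 1, graph$cellsize), c(1, 0, graph$cellsize))
  }
  out <- list()
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; d <- o[3]
    rows <- seq_len(nr - dr)
    cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    g <- expand.grid(row = rows, col = cols)
    from <- (g$row - 1L) * nc + g$col
    to <- (g$row - 1L + dr) * nc + g$col + dc
    ci <- cond[from]; cj <- cond[to]
    ok <- ci > 0 & cj > 0
    if (any(ok)) {
      out[[length(out) + 1L]] <-
        data.frame(from = pmin(from[ok], to[ok]),
                   to = pmax(from[ok], to[ok]),
                   weight = d / ((ci[ok] + cj[ok]) / 2))
    }
  }
  if (length(out) == 0) {
    return(data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$from, res$to), , drop = FALSE]
}

# snap a location to the nearest passable cell within `radius` cells
# (Euclidean center distance, ties by row-major index); error when none
snap_to_passable <- function(graph, x, y, radius = 5) {
  nc <- graph$ncol; nr <- graph$nrow; cs <- graph$cellsize
  col <- floor((x - graph$xmin) / cs) + 1L
  row <- nr - floor((y - graph$ymin) / cs)
  if (col < 1L || col > nc || row < 1L || row > nr)
    stop(sprintf("location (%g, %g) is outside the grid", x, y))
  if (graph$cond[row, col] > 0) return((row - 1L) * nc + col)
  rr <- max(1L, row - radius):min(nr, row + radius)
  cc <- max(1L, col - radius):min(nc, col + radius)
  g <- expand.grid(row = rr, col = cc)
  pass <- graph$cond[cbind(g$row, g$col)] > 0
  if (!any(pass))
    stop(sprintf("no passable cell within %d cells of (%g, %g)",
                 radius, x, y))
  g <- g[pass, , drop = FALSE]
  cx <- graph$xmin + (g$col - 0.5) * cs
  cy <- graph$ymin + (nr - g$row + 0.5) * cs
  d2 <- (cx - x)^2 + (cy - y)^2
  cand <- (g$row - 1L) * nc + g$col
  cand[order(d2, cand)][1]
}

path_from_parents <- function(graph, parent, src0, dst0) {
  cells <- dst0
  cur <- dst0
  while (cur != src0) {
    cur <- parent[cur + 1L]
    if (cur < 0) return(NULL)  # unreachable
    cells <- c(cur, cells)
  }
  nc <- graph$ncol; nr <- graph$nrow; cs <- graph$cellsize
  row <- cells %/% nc + 1L
  col <- cells %% nc + 1L
  cbind(x = graph$xmin + (col - 0.5) * cs,
        y = graph$ymin + (nr - row + 0.5) * cs)
}

#' Least-cost path between two locations
#'
#' Exact shortest path on the lattice graph (Dijkstra with a deterministic
#' tie-break preferring the lexicographically smallest predecessor cell).
#' Locations falling on a zero-conductance cell are snapped to the nearest
#' passable cell within `snap_radius` cells (an error beyond that).
#'
#' @param graph a [build_graph()] result.
#' @param src,dst length-2 `c(x, y)` locations.
#' @param snap_radius snapping radius in cells for impassable endpoints.
#' @return A `corridor_path`: list with `line` (matrix of cell-center
#'   vertices), `accumulated_cost` (conductance-weighted m),
#'   `euclidean_length` (m), `src_cell`, `dst_cell`.
#' @export
least_cost_path <- function(graph, src, dst, snap_radius = 5) {
  s0 <- snap_to_passable(graph, src[1], src[2], snap_radius) - 1L
  d0 <- snap_to_passable(graph, dst[1], dst[2], snap_radius) - 1L
  res <- cpp_dijkstra(graph$cond_rm, graph$nrow, graph$ncol,
                      graph$connectivity, graph$cellsize, s0)
  cost <- res$dist[d0 + 1L]
  if (!is.finite(cost))
    stop(sprintf("destination (%g, %g) is unreachable from (%g, %g)",
                 dst[1], dst[2], src[1], src[2]))
  line <- if (d0 == s0) {
    nc <- graph$ncol
    matrix(c(graph$xmin + (s0 %% nc + 0.5) * graph$cellsize,
             graph$ymin + (graph$nrow - s0 %/% nc - 0.5) * graph$cellsize),
           1, 2, dimnames = list(NULL, c("x", "y")))
  } else {
    path_from_parents(graph, res$parent, s0, d0)
  }
  structure(list(line = line, accumulated_cost = cost,
                 euclidean_length = polyline_length(line),
                 src_cell = s0 + 1L, dst_cell = d0 + 1L),
            class = "corridor_path")
}

#' Pair a start location with its k nearest end points
#'
#' Euclidean-distance k-nearest pairing (ties broken by end-point id).
#' When fewer than `k` end points exist, all are returned with a warning.
#'
#' @param start length-2 `c(x, y)` start location.
#' @param end_points data.frame with `end_point_id`, `x`, `y` (see
#'   [end_point_table()]).
#' @param k number of end points to pair (default 5).
#' @return `end_points` rows for the selected points, with a `distance`
#'   column, ordered by non-decreasing distance.
#' @export
k_nearest_end_points <- function(start, end_points, k = 5) {
  if (nrow(end_points) == 0) stop("no end points available for pairing")
  d <- sqrt((end_points$x - start[1])^2 + (end_points$y - start[2])^2)
  if (nrow(end_points) < k)
    warning(sprintf("only %d end points available (k = %d); using all",
                    nrow(end_points), k))
  ord <- order(d, end_points$end_point_id)
  take <- ord[seq_len(min(k, nrow(end_points)))]
  out <- end_points[take, , drop = FALSE]
  out$distance <- d[take]
  rownames(out) <- NULL
  out
}

#' Trace least-cost corridors for every start node
#'
#' Pairs each start node with its `k` nearest end points and traces the
#' least-cost path for each pair, computing one shortest-path tree per
#' start node (not per pair). Unreachable pairs are recorded with status
#' `"unreachable"` rather than failing the batch.
#'
#' @param graph a [build_graph()] result.
#' @param start_nodes data.frame from [identify_start_nodes()].
#' @param end_points data.frame from [end_point_table()].
#' @param k end points per start node (default 5).
#' @param snap_radius snapping radius (cells) for impassable endpoints.
#' @return A list with `paths` (named list of `corridor_path`, reachable
#'   pairs only) and `table` (one row per start/end pair: `corridor_id`,
#'   `start_id`, `end_point_id`, `patch_id`, `accumulated_cost`,
#'   `length_m`, `status`).
#' @export
batch_corridors <- function(graph, start_nodes, end_points, k = 5,
                            snap_radius = 5) {
  if (nrow(start_nodes) == 0) stop("no start nodes supplied")
  if (nrow(end_points) == 0) stop("no end points supplied")
  end_cells <- vapply(seq_len(nrow(end_points)), function(i) {
    as.integer(snap_to_passable(graph, end_points$x[i], end_points$y[i],
                                snap_radius))
  }, 0L)
  paths <- list()
  rows <- list()
  for (s in seq_len(nrow(start_nodes))) {
    sid <- start_nodes$reserve_id[s]
    start <- c(start_nodes$point_x[s], start_nodes$point_y[s])
    pairing <- k_nearest_end_points(start, end_points, k)
    s0 <- snap_to_passable(graph, start[1], start[2], snap_radius) - 1L
    res <- cpp_dijkstra(graph$cond_rm, graph$nrow, graph$ncol,
                        graph$connectivity, graph$cellsize, s0)
    for (e in seq_len(nrow(pairing))) {
      eid <- pairing$end_point_id[e]
      d0 <- end_cells[match(eid, end_points$end_point_id)] - 1L
      cid <- sprintf("S%s_E%s", sid, eid)
      cost <- res$dist[d0 + 1L]
      if (!is.finite(cost)) {
        rows[[length(rows) + 1L]] <-
          data.frame(corridor_id = cid, start_id = sid, end_point_id = eid,
                     patch_id = pairing$patch_id[e],
                     accumulated_cost = NA_real_, length_m = NA_real_,
                     status = "unreachable", stringsAsFactors = FALSE)
        next
      }
      line <- if (d0 == s0) {
        matrix(cell_xy_graph(graph, s0 + 1L), 1, 2,
               dimnames = list(NULL, c("x", "y")))
      } else {
        path_from_parents(graph, res$parent, s0, d0)
      }
      cp <- structure(list(line = line, accumulated_cost = cost,
                           euclidean_length = polyline_length(line),
                           src_cell = s0 + 1L, dst_cell = d0 + 1L,
                           start_id = sid, end_point_id = eid),
                      class = "corridor_path")
      paths[[cid]] <- cp
      rows[[length(rows) + 1L]] <-
        data.frame(corridor_id = cid, start_id = sid, end_point_id = eid,
                   patch_id = pairing$patch_id[e], accumulated_cost = cost,
                   length_m = cp$euclidean_length, status = "ok",
                   stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  n_bad <- sum(table$status != "ok")
  if (n_bad > 0)
    warning(sprintf("%d start/end pair(s) were unreachable", n_bad))
  list(paths = paths, table = table)
}

# center coordinates of a 1-based row-major cell index
cell_xy_graph <- function(graph, cell) {
  nc <- graph$ncol
  row <- (cell - 1L) %/% nc + 1L
  col <- (cell - 1L) %% nc + 1L
  c(graph$xmin + (col - 0.5) * graph$cellsize,
    graph$ymin + (graph$nrow - row + 0.5) * graph$cellsize)
}
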