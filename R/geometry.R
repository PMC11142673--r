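#' Planar polygon utilities
#'
#' Polygons are represented as two-column coordinate matrices (an open ring:
#' the last vertex implicitly joins the first). Multi-part geometries are
#' lists of such rings (holes are not supported). All coordinates are metric
#' and planar; the package never reprojects.
#'
#' @param poly a ring matrix or a list of ring matrices.
#' @return `polygon_area()`: area in m^2 (parts summed); `polygon_bbox()`:
#'   `c(xmin, xmax, ymin, ymax)`.
#' @export
polygon_area <- function(poly) {
  if (is.list(poly)) return(sum(vapply(poly, polygon_area, 0)))
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' @rdname polygon_area
#' @export
polygon_bbox <- function(poly) {
  if (is.list(poly)) poly <- do.call(rbind, poly)
  c(xmin = min(poly[, 1]), xmax = max(poly[, 1]),
    ymin = min(poly[, 2]), ymax = max(poly[, 2]))
}

#' Point-in-polygon test
#'
#' Even-odd (ray casting) containment for single- or multi-part polygons.
#'
#' @param pts two-column coordinate matrix of query points.
#' @param poly ring matrix or list of ring matrices.
#' @return Logical vector, one entry per query point.
#' @export
points_in_polygon <- function(pts, poly) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  if (is.list(poly)) {
    out <- rep(FALSE, nrow(pts))
    for (ring in poly) {
      out <- out | cpp_points_in_ring(pts[, 1], pts[, 2], ring[, 1], ring[, 2])
    }
    return(out)
  }
  cpp_points_in_ring(pts[, 1], pts[, 2], poly[, 1], poly[, 2])
}

# Sutherland-Hodgman clip of an arbitrary ring by the halfplane
# a*x + b*y <= c. Returns a ring matrix, or NULL when nothing remains.
clip_halfplane <- function(ring, a, b, cc) {
  if (is.null(ring) || nrow(ring) < 3) return(NULL)
  n <- nrow(ring)
  d <- a * ring[, 1] + b * ring[, 2] - cc
  out <- matrix(0, 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, ring[i, ])
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, ring[i, ] + t * (ring[j, ] - ring[i, ]))
    }
  }
  if (nrow(out) < 3 || polygon_area(out) <= 0) return(NULL)
  out
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Exact Sutherland-Hodgman clipping against a convex (rectangular) window;
#' used e.g. to retain the land portion of marine reserves and to keep
#' generated polygons inside the grid extent.
#'
#' @param poly ring matrix or list of rings.
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @return A ring matrix (or list of rings), or `NULL` when the intersection
#'   is empty.
#' @export
clip_polygon_rect <- function(poly, extent) {
  if (is.list(poly)) {
    parts <- Filter(Negate(is.null),
                    lapply(poly, clip_polygon_rect, extent = extent))
    if (length(parts) == 0) return(NULL)
    if (length(parts) == 1) return(parts[[1]])
    return(parts)
  }
  ring <- poly
  ring <- clip_halfplane(ring, -1, 0, -extent[1])  #  x >= xmin
  ring <- clip_halfplane(ring, 1, 0, extent[2])    #  x <= xmax
  ring <- clip_halfplane(ring, 0, -1, -extent[3])  #  y >= ymin
  ring <- clip_halfplane(ring, 0, 1, extent[4])    #  y <= ymax
  ring
}

#' Guaranteed-interior representative point
#'
#' Returns a point strictly inside the polygon, also for non-convex shapes
#' whose centroid falls outside. The point is the midpoint of the longest
#' interior interval of a horizontal scanline through the polygon (the
#' scanline is nudged off any vertex level). Multi-part geometries use the
#' largest part.
#'
#' @param poly ring matrix or list of rings.
#' @return Length-2 numeric vector `c(x, y)`.
#' @export
interior_point <- function(poly) {
  if (is.list(poly)) {
    areas <- vapply(poly, polygon_area, 0)
    poly <- poly[[which.max(areas)]]
  }
  if (is.null(poly) || nrow(poly) < 3 || polygon_area(poly) <= 0)
    stop("cannot place an interior point in an empty or zero-area polygon")
  ymin <- min(poly[, 2]); ymax <- max(poly[, 2])
  yspan <- ymax - ymin
  y <- (ymin + ymax) / 2
  # avoid scanlines through vertices (degenerate crossings)
  for (k in 0:50) {
    ycand <- y + k * yspan * 1e-4
    if (ycand >= ymax) ycand <- y - k * yspan * 1e-4
    if (min(abs(poly[, 2] - ycand)) > yspan * 1e-9) {
      y <- ycand
      break
    }
  }
  n <- nrow(poly)
  xs <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- poly[i, 2]; y2 <- poly[j, 2]
    if ((y1 > y) != (y2 > y)) {
      xs <- c(xs, poly[i, 1] + (y - y1) / (y2 - y1) * (poly[j, 1] - poly[i, 1]))
    }
  }
  xs <- sort(xs)
  if (length(xs) < 2) stop("degenerate polygon: scanline found no interior")
  starts <- xs[seq(1, length(xs) - 1, by = 2)]
  ends <- xs[seq(2, length(xs), by = 2)]
  k <- which.max(ends - starts)
  c(x = (starts[k] + ends[k]) / 2, y = y)
}

#' Voronoi partition of a rectangular extent
#'
#' Builds the Voronoi cell of each seed as the intersection of bisector
#' halfplanes with the extent rectangle (exact convex-polygon construction).
#' The cells partition the extent; used to generate synthetic country
#' boundaries.
#'
#' @param seeds two-column matrix of seed coordinates.
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @return List of convex ring matrices, one per seed.
#' @export
voronoi_polygons <- function(seeds, extent) {
  n <- nrow(seeds)
  rect <- rbind(c(extent[1], extent[3]), c(extent[2], extent[3]),
                c(extent[2], extent[4]), c(extent[1], extent[4]))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ring <- rect
    for (j in seq_len(n)) {
      if (i == j || is.null(ring)) next
      a <- 2 * (seeds[j, 1] - seeds[i, 1])
      b <- 2 * (seeds[j, 2] - seeds[i, 2])
      cc <- sum(seeds[j, ]^2) - sum(seeds[i, ]^2)
      ring <- clip_halfplane(ring, a, b, cc)
    }
    out[[i]] <- ring
  }
  out
}

#' Polyline length
#'
#' @param line two-column coordinate matrix of polyline vertices.
#' @return Total length in the coordinate units (m); 0 for a single vertex.
#' @export
polyline_length <- function(line) {
  if (!is.matrix(line)) line <- matrix(line, ncol = 2)
  if (nrow(line) < 2) return(0)
  sum(sqrt(rowSums(diff(line)^2)))
}

# segments of a polyline as parallel start/end coordinate vectors
polyline_segments <- function(line) {
  n <- nrow(line)
  if (n < 2) {
    return(list(x0 = line[1, 1], y0 = line[1, 2],
                x1 = line[1, 1], y1 = line[1, 2]))
  }
  list(x0 = line[-n, 1], y0 = line[-n, 2], x1 = line[-1, 1], y1 = line[-1, 2])
}

#' Minimum distance from points to a polyline
#'
#' @param pts two-column matrix of query points.
#' @param line two-column matrix of polyline vertices.
#' @param cutoff optional early-exit distance: scanning stops for a point
#'   once a distance `<= cutoff` is found (exact for containment tests at
#'   threshold `cutoff`). Use a negative value (default) for the exact
#'   minimum.
#' @return Numeric vector of distances (m).
#' @export
dist_to_polyline <- function(pts, line, cutoff = -1) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  s <- polyline_segments(line)
  cpp_min_dist_segments(pts[, 1], pts[, 2], s$x0, s$y0, s$x1, s$y1, cutoff)
}
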