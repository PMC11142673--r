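#' Buffer a corridor polyline
#'
#' Represents the fixed-width corridor swath: all points within
#' `half_width` of the polyline (round caps and joins by construction).
#' Containment against this region is exact (a distance predicate); the
#' explicit ring outline and the area are evaluated on a fine auxiliary
#' grid, see [buffer_area()] and [buffer_rings()]. The 1000 m default
#' half-width (2 km corridor width) is a rule-of-thumb minimum corridor
#' width for long-term gene flow.
#'
#' @param line two-column matrix of polyline vertices (>= 1 row; a single
#'   vertex yields a disc, reported with a message).
#' @param half_width buffer half-width in m, `> 0`.
#' @return An object of class `corridor_buffer`.
#' @export
buffer_polyline <- function(line, half_width = 1000) {
  if (!is.numeric(half_width) || length(half_width) != 1 || half_width <= 0)
    stop("half_width must be a single positive number")
  if (!is.matrix(line)) line <- matrix(line, ncol = 2)
  if (nrow(line) == 0) stop("empty polyline")
  if (nrow(line) == 1 || polyline_length(line) == 0)
    message("zero-length polyline: buffer degenerates to a disc")
  structure(list(line = line, half_width = half_width),
            class = "corridor_buffer")
}

#' @rdname buffer_polyline
#' @param buffer a `corridor_buffer`.
#' @param pts two-column matrix of query points.
#' @return `buffer_contains()`: logical vector (exact containment).
#' @export
buffer_contains <- function(buffer, pts) {
  dist_to_polyline(pts, buffer$line, cutoff = buffer$half_width) <=
    buffer$half_width
}

# fine auxiliary grid over the buffer bounding box
buffer_grid <- function(buffer, resolution) {
  bb <- c(min(buffer$line[, 1]), max(buffer$line[, 1]),
          min(buffer$line[, 2]), max(buffer$line[, 2]))
  hw <- buffer$half_width
  xs <- seq(bb[1] - hw - resolution / 2, bb[2] + hw + resolution / 2,
            by = resolution)
  ys <- seq(bb[3] - hw - resolution / 2, bb[4] + hw + resolution / 2,
            by = resolution)
  list(xs = xs, ys = ys)
}

#' Buffer area and outline
#'
#' `buffer_area()` estimates the buffer area by counting fine-grid cell
#' centers inside the buffer (cell size `resolution`, default
#' `half_width / 100`, i.e. 10 m for the standard 1000 m buffer).
#' `buffer_rings()` traces the buffer outline as rings (contours of the
#' distance field) for export.
#'
#' @param buffer a `corridor_buffer`.
#' @param resolution auxiliary grid cell size in m.
#' @return `buffer_area()`: area in m^2; `buffer_rings()`: list of ring
#'   matrices.
#' @export
buffer_area <- function(buffer, resolution = buffer$half_width / 100) {
  g <- buffer_grid(buffer, resolution)
  pts <- cbind(rep(g$xs, times = length(g$ys)),
               rep(g$ys, each = length(g$xs)))
  inside <- buffer_contains(buffer, pts)
  sum(inside) * resolution^2
}

#' @rdname buffer_area
#' @export
buffer_rings <- function(buffer, resolution = buffer$half_width / 20) {
  g <- buffer_grid(buffer, resolution)
  d <- matrix(dist_to_polyline(cbind(rep(g$xs, times = length(g$ys)),
                                     rep(g$ys, each = length(g$xs))),
                               buffer$line),
              length(g$xs), length(g$ys))
  cl <- contourLines(g$xs, g$ys, d, levels = buffer$half_width)
  lapply(cl, function(c1) cbind(c1$x, c1$y))
}

#' Corridor length
#'
#' Length of the corridor polyline itself (not its buffer), in km.
#'
#' @param line polyline vertex matrix (or a `corridor_path`).
#' @return Length in km (0 for a single vertex).
#' @export
corridor_length <- function(line) {
  if (inherits(line, "corridor_path")) line <- line$line
  polyline_length(line) / 1000
}

#' Cells of a raster covered by a region
#'
#' Resolves the package-wide zonal convention: the cells whose centers fall
#' inside the region. Regions may be polygons (ring matrix or list of
#' rings), raster-backed cell sets (end patches), or corridor buffers.
#'
#' @param region polygon, `cell_region`, `end_patch`, or `corridor_buffer`.
#' @param raster the target `grid_raster`.
#' @return Integer vector of row-major cell indices.
#' @export
region_cells <- function(region, raster) {
  if (inherits(region, "end_patch")) region <- region$region
  if (inherits(region, "cell_region")) {
    if (region$nrow != nrow(raster$values) ||
        region$ncol != ncol(raster$values) ||
        !isTRUE(all.equal(c(region$xmin, region$ymin, region$cellsize),
                          c(raster$xmin, raster$ymin, raster$cellsize))))
      stop("cell region and raster are not on the same grid")
    return(region$cells)
  }
  if (inherits(region, "corridor_buffer")) {
    hw <- region$half_width
    bb <- c(min(region$line[, 1]) - hw, max(region$line[, 1]) + hw,
            min(region$line[, 2]) - hw, max(region$line[, 2]) + hw)
    rect <- rbind(c(bb[1], bb[3]), c(bb[2], bb[3]),
                  c(bb[2], bb[4]), c(bb[1], bb[4]))
    cand <- polygon_cells(rect, raster)
    if (length(cand) == 0) return(integer(0))
    xy <- cell_xy(raster, cand)
    return(cand[dist_to_polyline(xy, region$line, cutoff = hw) <= hw])
  }
  polygon_cells(region, raster)
}

#' Zonal statistics under the cell-center convention
#'
#' `zonal_mean()` and `zonal_range()` summarize the raster cells whose
#' centers fall inside the region (mean, and max minus min respectively).
#'
#' @param region see [region_cells()].
#' @param raster a `grid_raster`.
#' @return A single numeric value (raster units).
#' @export
zonal_mean <- function(region, raster) {
  cells <- region_cells(region, raster)
  if (length(cells) == 0) stop("region covers no raster cell centers")
  mean(cell_value(raster, cells))
}

#' @rdname zonal_mean
#' @export
zonal_range <- function(region, raster) {
  cells <- region_cells(region, raster)
  if (length(cells) == 0) stop("region covers no raster cell centers")
  v <- cell_value(raster, cells)
  max(v) - min(v)
}

# which of the given cell centers fall inside any feature geometry
# (union-first semantics: a cell inside two overlapping features counts once)
cells_in_features <- function(xy, geometries) {
  inside <- rep(FALSE, nrow(xy))
  for (g in geometries) {
    todo <- which(!inside)
    if (length(todo) == 0) break
    bb <- polygon_bbox(g)
    cand <- todo[xy[todo, 1] >= bb["xmin"] & xy[todo, 1] <= bb["xmax"] &
                   xy[todo, 2] >= bb["ymin"] & xy[todo, 2] <= bb["ymax"]]
    if (length(cand) == 0) next
    inside[cand] <- points_in_polygon(xy[cand, , drop = FALSE], g)
  }
  inside
}

#' Percent protection of a region
#'
#' Share (0-100) of the region's cell centers lying inside the union of
#' the reserve polygons. Overlapping reserves are implicitly unioned (a
#' cell under several reserves counts once), so protection is never
#' double-counted.
#'
#' @param region see [region_cells()].
#' @param reserves cleaned reserve table (terrestrial portions).
#' @param template `grid_raster` fixing the zonal grid.
#' @return Percent in `[0, 100]`.
#' @export
percent_protection <- function(region, reserves, template) {
  cells <- region_cells(region, template)
  if (length(cells) == 0) stop("region covers no raster cell centers")
  xy <- cell_xy(template, cells)
  100 * mean(cells_in_features(xy, reserves$geometry))
}

#' Count features overlapping a region
#'
#' Number of distinct feature polygons sharing at least one region cell
#' center (the cell-center rasterization of "positive intersection area").
#' For protected-area counts, marine records are excluded.
#'
#' @param region see [region_cells()].
#' @param features polygon table with a `geometry` list-column (and a
#'   `marine` column when `exclude_marine`).
#' @param template `grid_raster` fixing the zonal grid.
#' @param exclude_marine drop features flagged `marine` before counting.
#' @return Integer count.
#' @export
count_overlaps <- function(region, features, template,
                           exclude_marine = FALSE) {
  if (exclude_marine) {
    if (!"marine" %in% names(features))
      stop("features table has no `marine` column")
    features <- features[!features$marine, , drop = FALSE]
  }
  cells <- region_cells(region, template)
  if (length(cells) == 0 || nrow(features) == 0) return(0L)
  xy <- cell_xy(template, cells)
  n <- 0L
  for (g in features$geometry) {
    bb <- polygon_bbox(g)
    cand <- xy[, 1] >= bb["xmin"] & xy[, 1] <= bb["xmax"] &
      xy[, 2] >= bb["ymin"] & xy[, 2] <= bb["ymax"]
    if (any(cand) &&
        any(points_in_polygon(xy[cand, , drop = FALSE], g))) n <- n + 1L
  }
  n
}

#' Countries crossed by a region and its primary country
#'
#' Assigns the region's cell centers to the country polygons; the number of
#' countries with at least one assigned cell and the country holding the
#' most cells (ties broken by lowest country id).
#'
#' @param region see [region_cells()].
#' @param countries country polygon table (partition of the extent).
#' @param template `grid_raster` fixing the zonal grid.
#' @return A list with `countries_crossed` (integer) and `primary_country`
#'   (country id).
#' @export
countries_summary <- function(region, countries, template) {
  cells <- region_cells(region, template)
  if (length(cells) == 0) stop("region covers no raster cell centers")
  xy <- cell_xy(template, cells)
  counts <- integer(nrow(countries))
  assigned <- rep(FALSE, nrow(xy))
  for (i in seq_len(nrow(countries))) {
    todo <- which(!assigned)
    if (length(todo) == 0) break
    inside <- points_in_polygon(xy[todo, , drop = FALSE],
                                countries$geometry[[i]])
    counts[i] <- sum(inside)
    assigned[todo[inside]] <- TRUE
  }
  if (all(counts == 0))
    stop("region lies outside every country polygon")
  ord <- order(-counts, countries$id)
  list(countries_crossed = sum(counts > 0L),
       primary_country = countries$id[ord[1]])
}

#' Corridor metric table
#'
#' Buffers every corridor polyline by `half_width` and computes the
#' corridor variable set: length (km, from the polyline itself),
#' elevational range (m), percent protection, number of overlapping
#' protected areas (marine excluded) and KBAs, mean forest biomass (Mt C;
#' over all buffer cells by default, zeros off-forest included), countries
#' crossed and primary country. All buffered variables use the cell-center
#' convention on the working grid. Unreachable pairs keep their row with
#' `NA` metrics and an explicit status (no silent drops).
#'
#' @param corridors result of [batch_corridors()].
#' @param dem,biomass aligned `grid_raster` layers.
#' @param reserves cleaned reserve table.
#' @param kbas KBA polygon table.
#' @param countries country polygon table.
#' @param half_width buffer half-width in m (default 1000).
#' @param landcover optional categorical raster; with
#'   `forest_only_biomass = TRUE`, biomass is averaged over forest-class
#'   buffer cells only.
#' @param forest_only_biomass average biomass over forest cells only.
#' @return A data.frame with one row per corridor (reachable or not).
#' @export
corridor_metrics <- function(corridors, dem, biomass, reserves, kbas,
                             countries, half_width = 1000,
                             landcover = NULL, forest_only_biomass = FALSE) {
  stop_if_misaligned(dem, biomass, what = "metric input rasters")
  if (forest_only_biomass && is.null(landcover))
    stop("forest_only_biomass requires the `landcover` raster")
  tab <- corridors$table
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    base <- data.frame(corridor_id = row$corridor_id,
                       start_id = row$start_id,
                       end_point_id = row$end_point_id,
                       patch_id = row$patch_id, status = row$status,
                       stringsAsFactors = FALSE)
    if (row$status != "ok") {
      out[[i]] <- cbind(base, length_km = NA_real_, elev_range = NA_real_,
                        protection = NA_real_, n_pas = NA_integer_,
                        n_kbas = NA_integer_, mean_biomass = NA_real_,
                        countries_crossed = NA_integer_,
                        primary_country = NA_integer_)
      next
    }
    path <- corridors$paths[[row$corridor_id]]
    buf <- suppressMessages(buffer_polyline(path$line, half_width))
    cells <- region_cells(buf, dem)
    elev <- cell_value(dem, cells)
    xy <- cell_xy(dem, cells)
    mb <- if (forest_only_biomass) {
      fc <- cell_value(landcover, cells) == forest_class_code()
      if (any(fc)) mean(cell_value(biomass, cells)[fc]) else 0
    } else {
      mean(cell_value(biomass, cells))
    }
    cs <- countries_summary(buf, countries, dem)
    out[[i]] <- cbind(base,
                      length_km = corridor_length(path$line),
                      elev_range = max(elev) - min(elev),
                      protection = 100 * mean(cells_in_features(
                        xy, reserves$geometry)),
                      n_pas = count_overlaps(buf, reserves, dem,
                                             exclude_marine = TRUE),
                      n_kbas = count_overlaps(buf, kbas, dem),
                      mean_biomass = mb,
                      countries_crossed = cs$countries_crossed,
                      primary_country = cs$primary_country)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Node attribute tables
#'
#' Computes, per start node and end patch, the node variable set: area
#' (km^2), elevational range (m), percent protection, and mean forest
#' biomass (Mt C). Start nodes are protected areas, so their protection is
#' 100 by construction; end-patch protection is measured against the
#' cleaned reserves.
#'
#' @param start_nodes data.frame from [identify_start_nodes()].
#' @param end_patches list from [extract_end_patches()].
#' @param dem,biomass aligned `grid_raster` layers.
#' @param reserves cleaned reserve table.
#' @return A list with data.frames `start` and `end`.
#' @export
node_metrics <- function(start_nodes, end_patches, dem, biomass, reserves) {
  start <- data.frame(reserve_id = start_nodes$reserve_id,
                      area_km2 = start_nodes$area_km2,
                      elev_range = start_nodes$elev_range,
                      protection = rep(100, nrow(start_nodes)),
                      mean_biomass = vapply(start_nodes$geometry,
                                            function(g) zonal_mean(g, biomass),
                                            0))
  end <- end_patch_table(end_patches)
  if (nrow(end) > 0) {
    end$protection <- vapply(end_patches, function(p) {
      percent_protection(p, reserves, dem)
    }, 0)
  } else {
    end$protection <- numeric(0)
  }
  list(start = start, end = end)
}
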