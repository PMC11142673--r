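#' Node-selection thresholds
#'
#' Thresholds governing start-node and end-patch selection. Defaults follow
#' the regional corridor design: start nodes are protected areas of at
#' least 5 km^2 with mean elevation at most 500 m; end patches are
#' contiguous forest of at least 5 km^2 with mean elevation at least
#' 1500 m passing a forest-integrity cutoff. `integrity_min` is expressed
#' on the synthetic 0-10 integrity scale (default 6, i.e. medium-or-better
#' integrity; supply your own cutoff for other integrity layers).
#' `hex_spacing` is the pitch (m) of the hexagonal end-point lattice; the
#' 3000 m default gives a ~5 km^2 patch a single representative point and a
#' point count that grows roughly linearly with patch area.
#'
#' @param min_start_area,min_end_area minimum areas (km^2), `> 0`.
#' @param lowland_elev_max,highland_elev_min elevation cutoffs (m);
#'   `highland_elev_min` must exceed `lowland_elev_max`.
#' @param integrity_min minimum integrity for end-patch cells (index units).
#' @param hex_spacing hexagonal sampling pitch (m), `> 0`.
#' @return A list of class `node_thresholds`.
#' @export
node_thresholds <- function(min_start_area = 5, lowland_elev_max = 500,
                            min_end_area = 5, highland_elev_min = 1500,
                            integrity_min = 6, hex_spacing = 3000) {
  if (min_start_area <= 0 || min_end_area <= 0)
    stop("area thresholds must be positive")
  if (highland_elev_min <= lowland_elev_max)
    stop("highland_elev_min must exceed lowland_elev_max")
  if (hex_spacing <= 0) stop("hex_spacing must be positive")
  structure(list(min_start_area = min_start_area,
                 lowland_elev_max = lowland_elev_max,
                 min_end_area = min_end_area,
                 highland_elev_min = highland_elev_min,
                 integrity_min = integrity_min, hex_spacing = hex_spacing),
            class = "node_thresholds")
}

# cells of `raster` whose centers fall inside the polygon (bbox-prefiltered)
polygon_cells <- function(poly, raster) {
  bb <- polygon_bbox(poly)
  ext <- raster_extent(raster)
  if (bb["xmax"] < ext["xmin"] || bb["xmin"] > ext["xmax"] ||
      bb["ymax"] < ext["ymin"] || bb["ymin"] > ext["ymax"])
    return(integer(0))
  cs <- raster$cellsize
  nc <- ncol(raster$values); nr <- nrow(raster$values)
  cmin <- max(1L, floor((bb["xmin"] - raster$xmin) / cs) + 1L)
  cmax <- min(nc, ceiling((bb["xmax"] - raster$xmin) / cs))
  rmin <- max(1L, nr - ceiling((bb["ymax"] - raster$ymin) / cs) + 1L)
  rmax <- min(nr, nr - floor((bb["ymin"] - raster$ymin) / cs))
  if (cmin > cmax || rmin > rmax) return(integer(0))
  grid <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  cells <- (grid$row - 1L) * nc + grid$col
  xy <- cell_xy(raster, cells)
  cells[points_in_polygon(xy, poly)]
}

# matrix values at row-major cell indices
cell_value <- function(raster, cells) {
  nc <- ncol(raster$values)
  row <- (cells - 1L) %/% nc + 1L
  col <- (cells - 1L) %% nc + 1L
  raster$values[cbind(row, col)]
}

#' Clean a reserve polygon table
#'
#' Applies the protected-area cleaning rules: duplicated geometries are
#' reduced to one record; records with "proposed" status, a 'UNESCO-MAB
#' Biosphere Reserve' designation, or unreported area are removed; marine
#' records are clipped to the land extent (their land portion retained,
#' records with no land portion dropped). The operation is idempotent.
#'
#' @param reserves reserve table with columns `id`, `status`, `designation`,
#'   `marine`, `reported_area`, and a `geometry` list-column.
#' @param land_extent `c(xmin, xmax, ymin, ymax)` of the terrestrial study
#'   extent (e.g. [raster_extent()] of the DEM); required when any marine
#'   record is present.
#' @return The cleaned reserve table.
#' @export
clean_reserves <- function(reserves, land_extent = NULL) {
  required <- c("id", "status", "designation", "marine", "reported_area",
                "geometry")
  missing_cols <- setdiff(required, names(reserves))
  if (length(missing_cols) > 0)
    stop("reserve table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  geom_key <- vapply(reserves$geometry, function(g) {
    if (is.list(g)) g <- do.call(rbind, g)
    paste(sprintf("%.17g", as.vector(g)), collapse = ",")
  }, "")
  out <- reserves[!duplicated(geom_key), , drop = FALSE]
  out <- out[out$status != "proposed", , drop = FALSE]
  out <- out[out$designation != "UNESCO-MAB Biosphere Reserve", , drop = FALSE]
  out <- out[!is.na(out$reported_area), , drop = FALSE]
  if (any(out$marine)) {
    if (is.null(land_extent))
      stop("`land_extent` is required to clip marine reserves to land")
    keep <- rep(TRUE, nrow(out))
    for (i in which(out$marine)) {
      clipped <- clip_polygon_rect(out$geometry[[i]], land_extent)
      if (is.null(clipped)) keep[i] <- FALSE else out$geometry[[i]] <- clipped
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Zonal mean elevation of a polygon
#'
#' Mean of the DEM cells whose centers fall inside the polygon (the
#' package-wide cell-center zonal convention).
#'
#' @param poly ring matrix or list of rings.
#' @param dem elevation `grid_raster` (m).
#' @return Mean elevation in m.
#' @export
polygon_mean_elevation <- function(poly, dem) {
  cells <- polygon_cells(poly, dem)
  if (length(cells) == 0)
    stop("polygon covers no raster cell centers (empty zone)")
  mean(cell_value(dem, cells))
}

#' Identify lowland start nodes
#'
#' Retains the cleaned reserves whose polygon area is at least
#' `min_start_area` km^2 and whose mean elevation is at most
#' `lowland_elev_max` m, and places one guaranteed-interior representative
#' point in each. Area is computed from the polygon geometry (the
#' `reported_area` attribute is only a cleaning criterion). Reserves whose
#' polygons cover no raster cell centers are skipped with a warning.
#'
#' @param reserves cleaned reserve table (see [clean_reserves()]).
#' @param dem elevation `grid_raster` (m).
#' @param thresholds a [node_thresholds()].
#' @return A data.frame of start nodes: `reserve_id`, `name`, `area_km2`,
#'   `mean_elev`, `elev_range`, `protection` (always 100), `point_x`,
#'   `point_y`, and the `geometry` list-column.
#' @export
identify_start_nodes <- function(reserves, dem,
                                 thresholds = node_thresholds()) {
  n <- nrow(reserves)
  keep <- logical(n)
  area <- mean_elev <- elev_range <- px <- py <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- reserves$geometry[[i]]
    a <- polygon_area(g) / 1e6
    cells <- polygon_cells(g, dem)
    if (length(cells) == 0) {
      warning(sprintf("reserve %s covers no cell centers; skipped",
                      reserves$id[i]))
      next
    }
    elev <- cell_value(dem, cells)
    area[i] <- a
    mean_elev[i] <- mean(elev)
    elev_range[i] <- max(elev) - min(elev)
    if (a >= thresholds$min_start_area &&
        mean_elev[i] <= thresholds$lowland_elev_max) {
      keep[i] <- TRUE
      pt <- interior_point(g)
      px[i] <- pt[1]; py[i] <- pt[2]
    }
  }
  if (!any(keep)) warning("no reserve qualifies as a start node")
  out <- data.frame(reserve_id = reserves$id[keep],
                    name = reserves$name[keep],
                    area_km2 = area[keep], mean_elev = mean_elev[keep],
                    elev_range = elev_range[keep],
                    protection = rep(100, sum(keep)),
                    point_x = px[keep], point_y = py[keep],
                    stringsAsFactors = FALSE)
  out$geometry <- reserves$geometry[keep]
  rownames(out) <- NULL
  out
}

# raster-backed cell region (used for end patches)
cell_region <- function(cells, template) {
  structure(list(cells = as.integer(cells),
                 xmin = template$xmin, ymin = template$ymin,
                 cellsize = template$cellsize,
                 nrow = nrow(template$values), ncol = ncol(template$values)),
            class = "cell_region")
}

# centers of region cells (row-major indices)
region_cell_xy <- function(region, cells) {
  nc <- region$ncol; nr <- region$nrow
  row <- (cells - 1L) %/% nc + 1L
  col <- (cells - 1L) %% nc + 1L
  cbind(x = region$xmin + (col - 0.5) * region$cellsize,
        y = region$ymin + (nr - row + 0.5) * region$cellsize)
}

# do points fall in cells belonging to the region?
cell_region_contains <- function(region, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  col <- floor((pts[, 1] - region$xmin) / region$cellsize) + 1L
  row <- region$nrow - floor((pts[, 2] - region$ymin) / region$cellsize)
  ok <- col >= 1L & col <= region$ncol & row >= 1L & row <= region$nrow
  cell <- (row - 1L) * region$ncol + col
  ok & (cell %in% region$cells)
}

#' Extract highland forest end patches
#'
#' End patches (target habitats) are connected components (8-connectivity
#' by default) of cells that are forest land cover with integrity at least
#' `integrity_min`, retained when their area is at least `min_end_area`
#' km^2 and their mean elevation is at least `highland_elev_min` m. Both
#' protected and unprotected patches are retained. Each patch carries a
#' representative interior point and hexagonally seeded end points (see
#' [seed_end_points()]).
#'
#' @param landcover,integrity,dem,biomass aligned `grid_raster` layers.
#' @param thresholds a [node_thresholds()].
#' @param connectivity patch contiguity, 8 (default) or 4.
#' @param forest_code land-cover code treated as forest.
#' @return A list of `end_patch` objects; see [end_patch_table()] for the
#'   attribute summary.
#' @export
extract_end_patches <- function(landcover, integrity, dem, biomass,
                                thresholds = node_thresholds(),
                                connectivity = 8,
                                forest_code = forest_class_code()) {
  stop_if_misaligned(landcover, integrity, dem, biomass,
                     what = "end-patch input rasters")
  v <- landcover$values
  mask <- !is.na(v) & v == forest_code &
    integrity$values >= thresholds$integrity_min
  lab <- cpp_label_components(as.vector(t(mask)), nrow(v), ncol(v),
                              as.integer(connectivity))
  if (max(lab) == 0) {
    message("no forest cells pass the integrity cutoff; no end patches")
    return(list())
  }
  cs <- landcover$cellsize
  patches <- list()
  pid <- 0L
  for (k in seq_len(max(lab))) {
    cells <- which(lab == k)  # row-major indices == cell ids
    area <- length(cells) * cs^2 / 1e6
    if (area < thresholds$min_end_area) next
    elev <- cell_value(dem, cells)
    if (mean(elev) < thresholds$highland_elev_min) next
    pid <- pid + 1L
    xy <- cell_xy(landcover, cells)
    ctr <- colMeans(xy)
    nearest <- which.min((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    patch <- structure(list(patch_id = pid, cells = cells,
                            region = cell_region(cells, landcover),
                            area_km2 = area, mean_elev = mean(elev),
                            elev_range = max(elev) - min(elev),
                            mean_biomass = mean(cell_value(biomass, cells)),
                            point = c(x = xy[nearest, 1], y = xy[nearest, 2])),
                       class = "end_patch")
    patch$seed_points <- seed_end_points(patch, thresholds$hex_spacing)
    patches[[pid]] <- patch
  }
  if (length(patches) == 0) message("no patch passes the area/elevation rules")
  patches
}

#' Hexagonal end-point seeding within a patch
#'
#' Lays a hexagonal lattice of pitch `hex_spacing` over the patch and keeps
#' the lattice points falling inside it, so that larger target habitats
#' receive proportionally more end points and least-cost paths need not
#' travel deep into large patches. Patches too small to catch any lattice
#' point receive their single interior representative point.
#'
#' @param patch an `end_patch` from [extract_end_patches()].
#' @param hex_spacing lattice pitch in m, `> 0`.
#' @return A two-column matrix of point coordinates (at least one row, all
#'   inside the patch).
#' @export
seed_end_points <- function(patch, hex_spacing = 3000) {
  if (!is.numeric(hex_spacing) || hex_spacing <= 0)
    stop("hex_spacing must be a positive number")
  xy <- region_cell_xy(patch$region, patch$cells)
  bb <- c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
  s <- hex_spacing
  dy <- s * sqrt(3) / 2
  seq_safe <- function(from, to, by) {
    if (from > to) numeric(0) else seq(from, to, by = by)
  }
  ys <- seq_safe(bb[3] + dy / 2, bb[4], dy)
  pts <- matrix(0, 0, 2)
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) s / 2 else 0
    xs <- seq_safe(bb[1] + s / 2 + off, bb[2], s)
    if (length(xs) > 0) pts <- rbind(pts, cbind(xs, ys[i]))
  }
  if (nrow(pts) > 0) pts <- pts[cell_region_contains(patch$region, pts), ,
                                drop = FALSE]
  if (nrow(pts) == 0) pts <- matrix(patch$point, 1, 2)
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

#' Summarize end patches as an attribute table
#'
#' @param patches list of `end_patch` objects.
#' @return A data.frame with one row per patch (`patch_id`, `area_km2`,
#'   `mean_elev`, `elev_range`, `mean_biomass`, `n_seed_points`, `point_x`,
#'   `point_y`).
#' @export
end_patch_table <- function(patches) {
  if (length(patches) == 0) {
    return(data.frame(patch_id = integer(0), area_km2 = numeric(0),
                      mean_elev = numeric(0), elev_range = numeric(0),
                      mean_biomass = numeric(0), n_seed_points = integer(0),
                      point_x = numeric(0), point_y = numeric(0)))
  }
  do.call(rbind, lapply(patches, function(p) {
    data.frame(patch_id = p$patch_id, area_km2 = p$area_km2,
               mean_elev = p$mean_elev, elev_range = p$elev_range,
               mean_biomass = p$mean_biomass,
               n_seed_points = nrow(p$seed_points),
               point_x = p$point["x"], point_y = p$point["y"],
               row.names = NULL)
  }))
}

#' Collect all end points across patches
#'
#' @param patches list of `end_patch` objects.
#' @return A data.frame with `end_point_id`, `patch_id`, `x`, `y`.
#' @export
end_point_table <- function(patches) {
  if (length(patches) == 0) {
    return(data.frame(end_point_id = integer(0), patch_id = integer(0),
                      x = numeric(0), y = numeric(0)))
  }
  tabs <- lapply(patches, function(p) {
    data.frame(patch_id = p$patch_id, x = p$seed_points[, 1],
               y = p$seed_points[, 2])
  })
  out <- do.call(rbind, tabs)
  out <- data.frame(end_point_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
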