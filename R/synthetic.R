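#' Land-cover class codes used by the synthetic generator
#'
#' A fixed eight-class set with WorldCover-like semantics. Conductance
#' lookups must cover every code present in a land-cover raster.
#'
#' @return A data.frame with columns `code` and `name`.
#' @export
landcover_classes <- function() {
  data.frame(code = c(10L, 20L, 30L, 40L, 50L, 60L, 80L, 90L),
             name = c("forest", "shrubland", "grassland", "cropland",
                      "built", "bare", "water", "wetland"))
}

#' @rdname landcover_classes
#' @export
forest_class_code <- function() 10L

#' Synthetic landscape configuration
#'
#' Bundles the parameters of the seeded synthetic-landscape generator. The
#' generated rasters share a planar grid with the origin at (0, 0); all
#' units are metric. The terrain is a lowland coastal plain (west) rising to
#' a highland massif (east), with a fragmented forest/agriculture mosaic,
#' biomass confined to forest, and a reserve table that deliberately
#' contains the pathological records (duplicates, proposed status,
#' UNESCO-MAB designation, marine polygons, unreported areas, sub-threshold
#' and highland reserves) that the cleaning and selection rules must handle.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 10 each).
#' @param cell_size cell edge length in m (default 100).
#' @param elev_max maximum elevation in m (>= 0).
#' @param n_reserves number of reserve polygons (>= 6; the first slots carry
#'   the guaranteed pathological records, the remainder are well-formed
#'   lowland reserves).
#' @param lowland_fraction fraction of the west-east gradient occupied by
#'   the flat lowland plain, in `[0, 1]`.
#' @param forest_fraction target fraction of forest cells, in `[0, 1]`.
#' @param biomass_mean,biomass_sd mean and sd of forest aboveground biomass
#'   (Mt C per cell); draws are truncated at 0.
#' @param n_countries number of Voronoi countries partitioning the extent.
#' @param n_kbas number of Key Biodiversity Area polygons.
#' @param seed integer seed; the same configuration and seed reproduce every
#'   output exactly.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(grid_rows = 200, grid_cols = 200,
                             cell_size = 100, elev_max = 3000,
                             n_reserves = 20, lowland_fraction = 0.25,
                             forest_fraction = 0.5, biomass_mean = 60,
                             biomass_sd = 30, n_countries = 3, n_kbas = 12,
                             seed = 1) {
  if (grid_rows < 10 || grid_cols < 10)
    stop("grid dimensions must be at least 10 x 10")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (elev_max < 0) stop("elev_max must be non-negative")
  if (lowland_fraction < 0 || lowland_fraction > 1)
    stop("lowland_fraction must be in [0, 1]")
  if (forest_fraction < 0 || forest_fraction > 1)
    stop("forest_fraction must be in [0, 1]")
  if (biomass_mean < 0) stop("biomass_mean must be non-negative")
  if (biomass_sd < 0) stop("biomass_sd must be non-negative")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, elev_max = elev_max,
                 n_reserves = as.integer(n_reserves),
                 lowland_fraction = lowland_fraction,
                 forest_fraction = forest_fraction,
                 biomass_mean = biomass_mean, biomass_sd = biomass_sd,
                 n_countries = as.integer(n_countries),
                 n_kbas = as.integer(n_kbas), seed = as.integer(seed)),
            class = "landscape_config")
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# independent sub-seed per generator stage, kept well below 2^31
stage_seed <- function(config, stage) {
  (abs(config$seed) %% 1000003L) * 101L + stage
}

# Gaussian-smoothed standard-normal noise field (separable band-matrix
# convolution with edge renormalization), rescaled to unit variance
smooth_noise_field <- function(nr, nc, sigma = 3) {
  band <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) {
      d <- abs(i - j)
      ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
    })
    K / rowSums(K)
  }
  z <- matrix(rnorm(nr * nc), nr, nc)
  s <- band(nr) %*% z %*% t(band(nc))
  s / stats::sd(as.vector(s))
}

# amplitude of the smoothed-noise relief relative to the unit lowland-highland
# ramp; small enough that lowland reserve means stay safely below 500 m
.relief_amplitude <- 0.03
.noise_sigma <- 3

#' Generate a synthetic digital elevation model
#'
#' Elevation is a west-to-east ramp (flat lowland plain over the first
#' `lowland_fraction` of the gradient, then a linear rise) plus
#' Gaussian-smoothed noise, rescaled exactly to `[0, elev_max]`. With
#' `elev_max >= 1500` the grid therefore always contains lowland (< 500 m)
#' and highland (> 1500 m) cells.
#'
#' @param config a [landscape_config()].
#' @return A `grid_raster` of elevations (m).
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (config$elev_max == 0) {
    return(grid_raster(matrix(0, nr, nc), cellsize = config$cell_size))
  }
  field <- with_seed(stage_seed(config, 1L), {
    t_ramp <- (seq_len(nc) - 0.5) / nc
    lf <- config$lowland_fraction
    base <- if (lf >= 1) rep(0, nc) else pmax(0, (t_ramp - lf) / (1 - lf))
    noise <- smooth_noise_field(nr, nc, .noise_sigma)
    matrix(base, nr, nc, byrow = TRUE) + .relief_amplitude * noise
  })
  field <- (field - min(field)) / (max(field) - min(field)) * config$elev_max
  grid_raster(field, cellsize = config$cell_size)
}

#' Generate synthetic categorical land cover
#'
#' Forest cells are the `forest_fraction` share of the grid with the highest
#' score, where the score is smoothed noise plus a strong bonus for highland
#' (`>= 1500` m) cells, producing clumped forest patches with highland
#' forest guaranteed whenever forest exists. A two-column non-forest strip
#' at mid-slope severs lowland from highland forest (the "matrix gap" that
#' corridors must cross). Remaining cells are a mosaic of cropland,
#' grassland, shrubland, built, water, bare, and wetland.
#'
#' @param dem `grid_raster` from [generate_dem()] on the same grid.
#' @param config the matching [landscape_config()].
#' @return A categorical `grid_raster` of class codes
#'   (see [landcover_classes()]).
#' @export
generate_landcover <- function(dem, config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (nrow(dem$values) != nr || ncol(dem$values) != nc)
    stop("dem grid does not match the configuration dimensions")
  n <- nr * nc
  f_total <- round(config$forest_fraction * n)
  lc <- with_seed(stage_seed(config, 2L), {
    score <- smooth_noise_field(nr, nc, .noise_sigma) + 2 * (dem$values >= 1500)
    ord <- order(as.vector(score), seq_len(n), decreasing = TRUE)
    out <- matrix(NA_integer_, nr, nc)
    is_forest <- logical(n)
    if (f_total > 0) is_forest[ord[seq_len(f_total)]] <- TRUE
    out[is_forest] <- forest_class_code()
    n_other <- sum(!is_forest)
    if (n_other > 0) {
      other_codes <- c(40L, 30L, 20L, 50L, 80L, 60L, 90L)
      probs <- c(0.40, 0.25, 0.15, 0.05, 0.05, 0.05, 0.05)
      out[!is_forest] <- sample(other_codes, n_other, TRUE, probs)
    }
    out
  })
  # mid-slope matrix gap: guarantees a non-forest band corridors must cross
  if (f_total > 0 && f_total < n) {
    lf <- config$lowland_fraction
    gap_t <- lf + 0.45 * (1 - lf)
    gap_col <- max(1L, min(nc - 1L, round(gap_t * nc)))
    lc[, gap_col + 0:1] <- 40L
  }
  grid_raster(lc, cellsize = config$cell_size)
}

#' Generate synthetic forest aboveground biomass
#'
#' Biomass is zero off-forest; forest cells draw from
#' `Normal(biomass_mean, biomass_sd)` truncated at 0 (Mt C per cell).
#'
#' @param landcover categorical `grid_raster` from [generate_landcover()].
#' @param config the matching [landscape_config()].
#' @return A `grid_raster` of biomass (Mt C).
#' @export
generate_biomass <- function(landcover, config) {
  stopifnot(inherits(config, "landscape_config"))
  if (config$biomass_mean < 0) stop("biomass_mean must be non-negative")
  v <- landcover$values
  forest <- !is.na(v) & v == forest_class_code()
  b <- matrix(0, nrow(v), ncol(v))
  nf <- sum(forest)
  if (nf > 0) {
    b[forest] <- with_seed(stage_seed(config, 3L),
                           pmax(0, rnorm(nf, config$biomass_mean,
                                         config$biomass_sd)))
  }
  grid_raster(b, xmin = landcover$xmin, ymin = landcover$ymin,
              cellsize = landcover$cellsize)
}

#' Generate a synthetic forest-integrity index
#'
#' A 0-10 index emulating a forest-intactness layer: forest cells center
#' around 8 with smoothed spatial variation (so a minority of forest falls
#' below a medium-integrity cutoff, in contiguous low-integrity pockets);
#' non-forest cells center around 2.
#'
#' @inheritParams generate_biomass
#' @return A `grid_raster` of integrity values in `[0, 10]`.
#' @export
generate_integrity <- function(landcover, config) {
  stopifnot(inherits(config, "landscape_config"))
  v <- landcover$values
  nr <- nrow(v); nc <- ncol(v)
  noise <- with_seed(stage_seed(config, 4L),
                     smooth_noise_field(nr, nc, .noise_sigma))
  forest <- !is.na(v) & v == forest_class_code()
  out <- matrix(0, nr, nc)
  out[forest] <- 8 + 1.5 * noise[forest]
  out[!forest] <- 2 + noise[!forest]
  out <- pmin(10, pmax(0, out))
  grid_raster(matrix(out, nr, nc), xmin = landcover$xmin,
              ymin = landcover$ymin, cellsize = landcover$cellsize)
}

# convex blob of the requested exact area around `center`
make_blob <- function(center, area_m2, nvert = 10) {
  ang <- sort(runif(nvert, 0, 2 * pi))
  rad <- sqrt(area_m2 / pi) * runif(nvert, 0.9, 1.1)
  pts <- cbind(center[1] + rad * cos(ang), center[2] + rad * sin(ang))
  hull <- pts[rev(grDevices::chull(pts)), , drop = FALSE]  # CCW ring
  ctr <- colMeans(hull)
  scale <- sqrt(area_m2 / polygon_area(hull))
  sweep(sweep(hull, 2, ctr) * scale, 2, ctr, "+")
}

#' Generate a synthetic protected-area polygon table
#'
#' Produces `n_reserves` convex reserve polygons with WDPA-like attributes
#' (`id`, `name`, `status`, `designation`, `marine`, `reported_area` in
#' km^2, and a `geometry` list-column of coordinate rings). The first slots
#' are fixed pathological fixtures that exercise every cleaning and
#' selection rule:
#' slot 1 a well-formed lowland reserve, slot 2 its byte-identical
#' duplicate, slot 3 "proposed" status, slot 4 a marine reserve straddling
#' the eastern (highland) grid edge whose land portion is below the area
#' threshold, slot 5 a 'UNESCO-MAB Biosphere Reserve' designation, slot 6 an
#' unreported-area record, slot 7 (when `n_reserves >= 7`) a sub-threshold
#' (~3 km^2) lowland reserve, and slot 8 (when `n_reserves >= 8`) a highland
#' reserve whose mean elevation exceeds 500 m. All remaining records are
#' well-formed lowland reserves of 7.5-12 km^2 that qualify as start nodes
#' under the default thresholds.
#'
#' @param dem `grid_raster` from [generate_dem()].
#' @param config the matching [landscape_config()]; `n_reserves >= 6`.
#' @return A data.frame reserve table.
#' @export
generate_reserves <- function(dem, config) {
  stopifnot(inherits(config, "landscape_config"))
  n <- config$n_reserves
  if (n < 6) stop("n_reserves must be at least 6 to carry the guaranteed fixture records")
  ext <- raster_extent(dem)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  lf <- config$lowland_fraction
  km2 <- 1e6
  with_seed(stage_seed(config, 5L), {
    # margin-aware placement: keep each blob inside the grid (and, where the
    # lowland plain is wide enough, fully on it); on grids too small for
    # that the blob is clamped as far in as possible and clipped below
    margin <- function(area_m2) 1.35 * sqrt(area_m2 / pi)
    pick <- function(lo, hi, m, len) {
      lo <- max(lo, m)
      hi <- max(min(hi, len - m), lo + 0.01 * len)
      if (hi <= lo) max(m, min(len - m, len / 2)) else runif(1, lo, hi)
    }
    low_x <- function(area_m2) {
      m <- margin(area_m2)
      ext["xmin"] + pick(0.03 * W, max(0.05, lf - 0.03) * W, m, W)
    }
    mid_y <- function(area_m2) {
      m <- margin(area_m2)
      ext["ymin"] + pick(0.12 * H, 0.88 * H, m, H)
    }
    geoms <- vector("list", n)
    status <- rep("designated", n)
    designation <- rep("National Park", n)
    marine <- rep(FALSE, n)
    reported <- rep(NA_real_, n)

    low_blob <- function(area_km2) {
      a <- area_km2 * km2
      clip_polygon_rect(make_blob(c(low_x(a), mid_y(a)), a), ext)
    }
    geoms[[1]] <- low_blob(8)
    reported[1] <- 8
    geoms[[2]] <- geoms[[1]]  # byte-identical duplicate geometry
    reported[2] <- 8
    geoms[[3]] <- low_blob(7)
    status[3] <- "proposed"; reported[3] <- 7
    # marine record straddling the eastern (highland) edge; small land part
    geoms[[4]] <- make_blob(c(ext["xmax"] + 0.2 * sqrt(4 * km2 / pi),
                              mid_y(4 * km2)), 4 * km2)
    marine[4] <- TRUE; reported[4] <- 4
    geoms[[5]] <- low_blob(9)
    designation[5] <- "UNESCO-MAB Biosphere Reserve"; reported[5] <- 9
    geoms[[6]] <- low_blob(8)
    reported[6] <- NA_real_  # unreported area
    if (n >= 7) {
      geoms[[7]] <- low_blob(3)
      reported[7] <- 3
    }
    if (n >= 8) {
      a8 <- 8 * km2
      hx <- ext["xmin"] + pick(0.82 * W, 0.90 * W, margin(a8), W)
      geoms[[8]] <- clip_polygon_rect(make_blob(c(hx, mid_y(a8)), a8), ext)
      reported[8] <- 8
    }
    if (n >= 9) {
      for (i in 9:n) {
        a <- runif(1, 7.5, 12)
        geoms[[i]] <- low_blob(a)
        reported[i] <- round(a, 2)
      }
    }
    out <- data.frame(id = seq_len(n),
                      name = sprintf("Reserve %03d", seq_len(n)),
                      status = status, designation = designation,
                      marine = marine, reported_area = reported,
                      stringsAsFactors = FALSE)
    out$geometry <- geoms
    out
  })
}

#' Generate synthetic Key Biodiversity Areas
#'
#' @inheritParams generate_reserves
#' @return A data.frame with `id`, `name`, and a `geometry` list-column.
#' @export
generate_kbas <- function(dem, config) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- raster_extent(dem)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  n <- config$n_kbas
  with_seed(stage_seed(config, 6L), {
    geoms <- lapply(seq_len(max(n, 0)), function(i) {
      ctr <- c(ext["xmin"] + runif(1, 0.05, 0.95) * W,
               ext["ymin"] + runif(1, 0.05, 0.95) * H)
      ring <- make_blob(ctr, runif(1, 3, 20) * 1e6)
      clip_polygon_rect(ring, ext)
    })
    keep <- !vapply(geoms, is.null, TRUE)
    out <- data.frame(id = seq_len(n)[keep],
                      name = sprintf("KBA %03d", seq_len(n)[keep]),
                      stringsAsFactors = FALSE)
    out$geometry <- geoms[keep]
    out
  })
}

#' Generate synthetic country polygons
#'
#' Countries partition the grid extent by the Voronoi tessellation of random
#' seed points (exact convex polygons).
#'
#' @inheritParams generate_reserves
#' @return A data.frame with `id`, `name`, and a `geometry` list-column.
#' @export
generate_countries <- function(dem, config) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- raster_extent(dem)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  n <- max(1L, config$n_countries)
  with_seed(stage_seed(config, 7L), {
    seeds <- cbind(ext["xmin"] + runif(n, 0.1, 0.9) * W,
                   ext["ymin"] + runif(n, 0.1, 0.9) * H)
    polys <- voronoi_polygons(seeds, ext)
    out <- data.frame(id = seq_len(n),
                      name = sprintf("Country %02d", seq_len(n)),
                      stringsAsFactors = FALSE)
    out$geometry <- polys
    out
  })
}

#' Generate a complete synthetic landscape
#'
#' Runs every generator on a shared grid and returns the aligned raster
#' stack plus the polygon tables. Deterministic: the same configuration
#' (including its seed) reproduces every output exactly.
#'
#' @param config a [landscape_config()].
#' @return A list of class `synthetic_landscape` with elements `dem`,
#'   `landcover`, `biomass`, `integrity`, `reserves`, `kbas`, `countries`,
#'   and `config`.
#' @export
generate_landscape <- function(config) {
  dem <- generate_dem(config)
  landcover <- generate_landcover(dem, config)
  biomass <- generate_biomass(landcover, config)
  integrity <- generate_integrity(landcover, config)
  stop_if_misaligned(dem, landcover, biomass, integrity,
                     what = "generated rasters")
  structure(list(dem = dem, landcover = landcover, biomass = biomass,
                 integrity = integrity,
                 reserves = generate_reserves(dem, config),
                 kbas = generate_kbas(dem, config),
                 countries = generate_countries(dem, config),
                 config = config),
            class = "synthetic_landscape")
}
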