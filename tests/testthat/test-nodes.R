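test_that("reserve cleaning applies each rule and is idempotent", {
  ext <- c(0, 10000, 0, 10000)
  tab <- rbind(
    reserve_row(1, rect_ring(0, 0, 3000, 3000)),
    reserve_row(2, rect_ring(0, 0, 3000, 3000)),  # duplicate geometry
    reserve_row(3, rect_ring(4000, 0, 7000, 3000), status = "proposed"),
    reserve_row(4, rect_ring(0, 4000, 3000, 7000),
                designation = "UNESCO-MAB Biosphere Reserve"),
    reserve_row(5, rect_ring(4000, 4000, 7000, 7000),
                reported_area = NA_real_),
    reserve_row(6, rect_ring(8000, 8000, 14000, 14000), marine = TRUE))
  out <- clean_reserves(tab, ext)
  expect_setequal(out$id, c(1, 6))
  # marine record keeps only its land portion
  expect_equal(polygon_area(out$geometry[[which(out$id == 6)]]),
               2000 * 2000)
  expect_identical(clean_reserves(out, ext), out)
  # 1 designated + 1 proposed -> 1 retained
  two <- rbind(reserve_row(1, rect_ring(0, 0, 1000, 1000)),
               reserve_row(2, rect_ring(2000, 0, 3000, 1000),
                           status = "proposed"))
  expect_equal(clean_reserves(two, ext)$id, 1)
  # schema violations name the missing column
  expect_error(clean_reserves(two[setdiff(names(two), "status")], ext),
               "status")
})

test_that("cleaning a generated fixture equals a per-record rule re-check", {
  cfg <- landscape_config(grid_rows = 100, grid_cols = 100, n_reserves = 10,
                          seed = 5)
  dem <- generate_dem(cfg)
  res <- generate_reserves(dem, cfg)
  out <- clean_reserves(res, raster_extent(dem))
  key <- vapply(res$geometry, function(g) {
    paste(sprintf("%.17g", as.vector(g)), collapse = ",")
  }, "")
  ok <- !duplicated(key) & res$status != "proposed" &
    res$designation != "UNESCO-MAB Biosphere Reserve" &
    !is.na(res$reported_area)
  expect_setequal(out$id, res$id[ok])
})

test_that("zonal mean elevation follows the cell-center rule exactly", {
  flat <- grid_raster(matrix(300, 10, 10), cellsize = 100)
  expect_equal(polygon_mean_elevation(rect_ring(100, 100, 700, 800), flat),
               300)
  # two specific cells valued 100 and 500
  v <- matrix(0, 4, 4)
  v[4, 1] <- 100; v[4, 2] <- 500  # bottom row cells at x 0-100, 100-200
  r <- grid_raster(v, cellsize = 100)
  expect_equal(polygon_mean_elevation(rect_ring(0, 0, 200, 100), r), 300)
  # irregular polygon vs exhaustive loop over every cell center
  set.seed(21)
  dem <- grid_raster(matrix(runif(2500, 0, 2000), 50, 50), cellsize = 100)
  poly <- rbind(c(320, 410), c(4350, 150), c(4820, 3950), c(2300, 4700),
                c(600, 3100))
  got <- polygon_mean_elevation(poly, dem)
  xy <- cell_centers(dem)
  inside <- points_in_polygon(xy, poly)
  expect_equal(got, mean(cell_value(dem, which(inside))))
  expect_error(polygon_mean_elevation(rect_ring(10, 10, 20, 20), dem),
               "empty zone")
})

test_that("start-node selection honors area and elevation boundaries", {
  dem <- grid_raster(matrix(200, 60, 60), cellsize = 100)
  ext <- raster_extent(dem)
  side_small <- sqrt(4.9e6)
  tab <- rbind(
    reserve_row(1, rect_ring(100, 100, 100 + side_small,
                             100 + side_small)),        # 4.9 km2: too small
    reserve_row(2, rect_ring(100, 3000, 3100, 3000 + 10e6 / 3000)))
  sel <- identify_start_nodes(tab, dem)
  expect_equal(sel$reserve_id, 2)
  expect_equal(sel$protection, 100)
  # 10 km2 at mean 501 m: excluded by the elevation rule
  dem501 <- grid_raster(matrix(501, 60, 60), cellsize = 100)
  expect_warning(sel2 <- identify_start_nodes(tab, dem501), "no reserve")
  expect_equal(nrow(sel2), 0)
  # boundary inclusivity: exactly 5 km2 at exactly 500 m qualifies
  dem500 <- grid_raster(matrix(500, 60, 60), cellsize = 100)
  tab5 <- reserve_row(9, rect_ring(0, 0, 2500, 2000))
  expect_equal(identify_start_nodes(tab5, dem500)$reserve_id, 9)
})

test_that("start-node selection equals the brute-force filter on fixtures", {
  for (seed in c(5, 11)) {
    cfg <- landscape_config(grid_rows = 120, grid_cols = 120,
                            n_reserves = 12, seed = seed)
    ls <- generate_landscape(cfg)
    clean <- clean_reserves(ls$reserves, raster_extent(ls$dem))
    sel <- identify_start_nodes(clean, ls$dem)
    expected <- clean$id[vapply(seq_len(nrow(clean)), function(i) {
      g <- clean$geometry[[i]]
      cells <- polygon_cells(g, ls$dem)
      length(cells) > 0 && polygon_area(g) / 1e6 >= 5 &&
        mean(cell_value(ls$dem, cells)) <= 500
    }, TRUE)]
    expect_setequal(sel$reserve_id, expected)
    # representative points are strictly inside their reserves
    for (i in seq_len(nrow(sel))) {
      expect_true(points_in_polygon(cbind(sel$point_x[i], sel$point_y[i]),
                                    sel$geometry[[i]]))
    }
  }
})

test_that("end patches respect forest, integrity, area, elevation, and connectivity", {
  base <- tiny_landscape()
  th <- node_thresholds()
  patches <- extract_end_patches(base$landcover, base$integrity, base$dem,
                                 base$biomass, th)
  expect_gte(length(patches), 1)
  for (p in patches) {
    expect_gte(p$area_km2, 5)
    expect_gte(p$mean_elev, 1500)
    cells <- p$cells
    expect_true(all(cell_value(base$landcover, cells) ==
                      forest_class_code()))
    expect_true(all(cell_value(base$integrity, cells) >= th$integrity_min))
  }
  # a 6 km2 highland block at mean 1400 m is excluded
  low <- tiny_landscape()
  low$dem <- grid_raster(matrix(1400, 40, 60), cellsize = 100)
  expect_length(suppressMessages(
    extract_end_patches(low$landcover, low$integrity, low$dem,
                        low$biomass, th)), 0)
  # corner-touching blocks merge under 8-connectivity, split under 4
  lc <- matrix(40L, 50, 50)
  lc[1:25, 1:25] <- 10L
  lc[26:50, 26:50] <- 10L
  corner <- list(landcover = grid_raster(lc, cellsize = 100),
                 integrity = grid_raster(matrix(9, 50, 50), cellsize = 100),
                 dem = grid_raster(matrix(1600, 50, 50), cellsize = 100),
                 biomass = grid_raster(matrix(50, 50, 50), cellsize = 100))
  p8 <- extract_end_patches(corner$landcover, corner$integrity, corner$dem,
                            corner$biomass, th, connectivity = 8)
  p4 <- extract_end_patches(corner$landcover, corner$integrity, corner$dem,
                            corner$biomass, th, connectivity = 4)
  expect_length(p8, 1)
  expect_length(p4, 2)
})

test_that("no start node can double as an end patch under the defaults", {
  cfg <- landscape_config(grid_rows = 120, grid_cols = 120, n_reserves = 10,
                          seed = 3)
  ls <- generate_landscape(cfg)
  clean <- clean_reserves(ls$reserves, raster_extent(ls$dem))
  sn <- identify_start_nodes(clean, ls$dem)
  ep <- extract_end_patches(ls$landcover, ls$integrity, ls$dem, ls$biomass)
  for (p in ep) expect_gt(p$mean_elev, max(sn$mean_elev))
})

test_that("hexagonal seeding matches a brute-force lattice clip", {
  # square patch of side 10 s with spacing s
  s <- 500
  lc <- matrix(10L, 60, 60)
  r <- grid_raster(lc, cellsize = 100)
  patch <- structure(list(patch_id = 1L,
                          cells = seq_len(3600),
                          region = climcorridor:::cell_region(seq_len(3600), r),
                          point = c(x = 3000, y = 3000)),
                     class = "end_patch")
  pts <- seed_end_points(patch, s)
  # oracle: enumerate the full lattice over the bbox and clip
  dy <- s * sqrt(3) / 2
  ys <- seq(50 + dy / 2, 5950, by = dy)
  n_ref <- 0
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) s / 2 else 0
    xs <- seq(50 + s / 2 + off, 5950, by = s)
    n_ref <- n_ref + sum(xs >= 0 & xs <= 6000)
  }
  expect_equal(nrow(pts), n_ref)
  # patch smaller than one hex cell gets exactly its interior point
  small <- structure(list(patch_id = 2L, cells = 1:3,
                          region = climcorridor:::cell_region(1:3, r),
                          point = c(x = 150, y = 5950)),
                     class = "end_patch")
  one <- seed_end_points(small, 3000)
  expect_equal(nrow(one), 1)
  expect_error(seed_end_points(small, -1), "positive")
  # containment invariant on a generated patch
  base <- tiny_landscape()
  patches <- extract_end_patches(base$landcover, base$integrity, base$dem,
                                 base$biomass)
  for (p in patches) {
    expect_true(all(climcorridor:::cell_region_contains(p$region,
                                                        p$seed_points)))
  }
})
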