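test_that("buffer containment is exact and area matches closed forms", {
  # straight 10 km segment, 1000 m buffer: rectangle plus two end caps
  line <- rbind(c(0, 0), c(10000, 0))
  buf <- buffer_polyline(line, 1000)
  expect_true(all(buffer_contains(buf, rbind(c(5000, 999), c(0, -999),
                                             c(10900, 0)))))
  expect_false(any(buffer_contains(buf, rbind(c(5000, 1001), c(-1001, 0)))))
  analytic <- 2 * 1000 * 10000 + pi * 1000^2
  expect_equal(buffer_area(buf), analytic, tolerance = 0.005)
  # zero-length line degenerates to a disc (logged)
  expect_message(disc <- buffer_polyline(rbind(c(0, 0)), 1000),
                 "disc")
  expect_equal(buffer_area(disc), pi * 1000^2, tolerance = 0.005)
  expect_error(buffer_polyline(line, 0), "positive")
})

test_that("L-shaped buffer area matches a Monte-Carlo estimate within 1%", {
  line <- rbind(c(0, 0), c(4000, 0), c(4000, 3000))
  buf <- buffer_polyline(line, 1000)
  got <- buffer_area(buf)
  set.seed(77)
  n <- 200000
  pts <- cbind(runif(n, -1100, 5100), runif(n, -1100, 4100))
  mc <- mean(dist_to_polyline(pts, line) <= 1000) * (6200 * 5200)
  expect_equal(got, mc, tolerance = 0.01)
})

test_that("corridor length sums the polyline segments", {
  line <- cbind(seq(0, 400, by = 100), 0)
  expect_equal(corridor_length(line), 0.4)
  expect_equal(corridor_length(matrix(c(1, 1), 1, 2)), 0)
  set.seed(8)
  rnd <- cbind(cumsum(runif(20, 0, 500)), cumsum(rnorm(20, 0, 200)))
  expect_equal(corridor_length(rnd),
               sum(sqrt(diff(rnd[, 1])^2 + diff(rnd[, 2])^2)) / 1000)
})

test_that("zonal statistics equal exhaustive cell-center loops", {
  flat <- grid_raster(matrix(7, 20, 20), cellsize = 100)
  sq <- rect_ring(200, 200, 900, 1100)
  expect_equal(zonal_range(sq, flat), 0)
  expect_equal(zonal_mean(sq, flat), 7)
  # three specific cells
  v <- matrix(0, 1, 3)
  v[1, ] <- c(100, 250, 900)
  r3 <- grid_raster(v, cellsize = 100)
  strip <- rect_ring(0, 0, 300, 100)
  expect_equal(zonal_range(strip, r3), 800)
  expect_equal(zonal_mean(strip, r3), mean(c(100, 250, 900)))
  # irregular polygon on a random raster vs the exhaustive oracle
  set.seed(13)
  rr <- grid_raster(matrix(runif(10000, 0, 500), 100, 100), cellsize = 100)
  poly <- rbind(c(500, 300), c(9200, 800), c(8700, 9100), c(4000, 9700),
                c(300, 5000))
  inside <- points_in_polygon(cell_centers(rr), poly)
  vals <- cell_value(rr, which(inside))
  expect_equal(zonal_mean(poly, rr), mean(vals))
  expect_equal(zonal_range(poly, rr), max(vals) - min(vals))
  expect_error(zonal_mean(rect_ring(20, 20, 40, 40), rr), "no raster cell")
})

test_that("buffer zonal cells equal a brute-force distance scan", {
  set.seed(19)
  r <- grid_raster(matrix(runif(3600), 60, 60), cellsize = 100)
  line <- rbind(c(500, 500), c(2500, 1500), c(3000, 4000))
  buf <- buffer_polyline(line, 1000)
  got <- sort(region_cells(buf, r))
  xy <- cell_centers(r)
  ref <- which(dist_to_polyline(xy, line) <= 1000)
  expect_equal(got, ref)
})

test_that("percent protection uses exact union-first areas", {
  template <- grid_raster(matrix(0, 40, 40), cellsize = 100)
  buf <- rect_ring(0, 0, 2000, 2000)
  # fully covered
  full <- reserve_row(1, rect_ring(-100, -100, 2100, 2100))
  expect_equal(percent_protection(buf, full, template), 100)
  # one reserve covering exactly half
  half <- reserve_row(1, rect_ring(0, 0, 1000, 2000))
  expect_equal(percent_protection(buf, half, template), 50)
  # two coincident reserves over the same half still give 50, not 100
  twice <- rbind(reserve_row(1, rect_ring(0, 0, 1000, 2000)),
                 reserve_row(2, rect_ring(0, 0, 1000, 2000)))
  expect_equal(percent_protection(buf, twice, template), 50)
  # splitting a reserve into two adjacent halves changes nothing
  split2 <- rbind(reserve_row(1, rect_ring(0, 0, 1000, 1000)),
                  reserve_row(2, rect_ring(0, 1000, 1000, 2000)))
  expect_equal(percent_protection(buf, split2, template),
               percent_protection(buf, half, template))
})

test_that("overlap counts respect the marine exclusion and disjointness", {
  template <- grid_raster(matrix(0, 40, 40), cellsize = 100)
  buf <- rect_ring(0, 0, 2000, 2000)
  feats <- rbind(
    reserve_row(1, rect_ring(500, 500, 1500, 1500)),
    reserve_row(2, rect_ring(1500, 0, 2500, 900)),
    reserve_row(3, rect_ring(0, 1500, 600, 2500), marine = TRUE),
    reserve_row(4, rect_ring(3000, 3000, 3900, 3900)))  # disjoint
  expect_equal(count_overlaps(buf, feats, template, exclude_marine = TRUE),
               2)
  expect_equal(count_overlaps(buf, feats, template), 3)
  expect_equal(count_overlaps(buf, feats[4, ], template), 0)
  # adding a disjoint reserve never decreases protection or the PA count
  p1 <- percent_protection(buf, feats[1, ], template)
  p2 <- percent_protection(buf, feats[c(1, 4), ], template)
  expect_gte(p2, p1)
})

test_that("country crossing counts and primary assignment are exact", {
  template <- grid_raster(matrix(0, 40, 40), cellsize = 100)
  countries <- data.frame(id = 1:2, name = c("A", "B"),
                          stringsAsFactors = FALSE)
  # split 70/30 along x = 1400 within a 2000 m buffer square
  countries$geometry <- list(rect_ring(0, 0, 1400, 4000),
                             rect_ring(1400, 0, 4000, 4000))
  buf <- rect_ring(0, 0, 2000, 2000)
  cs <- countries_summary(buf, countries, template)
  expect_equal(cs$countries_crossed, 2)
  expect_equal(cs$primary_country, 1)
  # fully inside one country
  cs2 <- countries_summary(rect_ring(1500, 0, 2000, 500), countries,
                           template)
  expect_equal(cs2$countries_crossed, 1)
  expect_equal(cs2$primary_country, 2)
  # equal split ties break to the lowest id
  cs3 <- countries_summary(rect_ring(400, 0, 2400, 1000), countries,
                           template)
  expect_equal(cs3$primary_country, 1)
  expect_error(countries_summary(rect_ring(0, 0, 100, 100),
                                 data.frame(id = 1, name = "A",
                                            geometry = I(list(
                                              rect_ring(3900, 3900, 4000, 4000)))),
                                 template),
               "outside every country")
})

test_that("corridor metric tables keep one row per pair with status", {
  base <- tiny_landscape()
  th <- node_thresholds()
  reserves <- rbind(
    reserve_row(1, rect_ring(100, 100, 2800, 2300)),
    reserve_row(2, rect_ring(100, 2500, 2800, 3900)))
  clean <- clean_reserves(reserves, raster_extent(base$dem))
  sn <- identify_start_nodes(clean, base$dem, th)
  ep <- extract_end_patches(base$landcover, base$integrity, base$dem,
                            base$biomass, th)
  ept <- end_point_table(ep)
  surf <- build_conductance(base$landcover,
                            conductance_lookup(data.frame(
                              class_code = c(10L, 40L),
                              conductance = c(1, 0.4),
                              is_forest = c(TRUE, FALSE))),
                            biomass_modifier(base$biomass))
  suppressWarnings(cor <- batch_corridors(build_graph(surf), sn, ept, k = 2))
  countries <- data.frame(id = 1L, name = "A", stringsAsFactors = FALSE)
  countries$geometry <- list(rect_ring(0, 0, 6000, 4000))
  kbas <- reserve_row(1, rect_ring(3000, 0, 4500, 4000))
  met <- corridor_metrics(cor, base$dem, base$biomass, clean, kbas,
                          countries)
  expect_equal(nrow(met), nrow(cor$table))
  ok <- met$status == "ok"
  expect_true(all(met$length_km[ok] > 0))
  expect_true(all(met$protection[ok] >= 0 & met$protection[ok] <= 100))
  expect_true(all(met$countries_crossed[ok] == 1))
  expect_true(all(met$primary_country[ok] == 1))
  # buffers contain their polylines
  for (cid in names(cor$paths)) {
    p <- cor$paths[[cid]]
    buf <- buffer_polyline(p$line, 1000)
    expect_true(all(buffer_contains(buf, p$line)))
  }
})

test_that("node metric tables carry the constructed protection levels", {
  base <- tiny_landscape()
  th <- node_thresholds()
  reserves <- reserve_row(1, rect_ring(100, 100, 2800, 2300))
  clean <- clean_reserves(reserves, raster_extent(base$dem))
  sn <- identify_start_nodes(clean, base$dem, th)
  ep <- extract_end_patches(base$landcover, base$integrity, base$dem,
                            base$biomass, th)
  nm <- node_metrics(sn, ep, base$dem, base$biomass, clean)
  expect_true(all(nm$start$protection == 100))
  # highland patches lie entirely outside the lowland reserve
  expect_true(all(nm$end$protection == 0))
  # half-covered patch reads 50
  lc <- matrix(40L, 40, 40)
  lc[, 21:40] <- 10L
  half <- list(landcover = grid_raster(lc, cellsize = 100),
               integrity = grid_raster(matrix(9, 40, 40), cellsize = 100),
               dem = grid_raster(matrix(1600, 40, 40), cellsize = 100),
               biomass = grid_raster(matrix(50, 40, 40), cellsize = 100))
  hp <- extract_end_patches(half$landcover, half$integrity, half$dem,
                            half$biomass, th)
  cover <- reserve_row(7, rect_ring(2000, 0, 3000, 4000))
  nm2 <- node_metrics(sn[0, ], hp, half$dem, half$biomass,
                      clean_reserves(cover, raster_extent(half$dem)))
  expect_equal(nm2$end$protection, 50)
})
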