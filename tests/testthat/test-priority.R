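make_tables <- function(n = 30, seed = 1) {
  set.seed(seed)
  corridor <- data.frame(
    corridor_id = sprintf("S%d_E1", 1:n), start_id = 1:n,
    end_point_id = 1L, patch_id = 1L, status = "ok",
    length_km = runif(n, 10, 400), elev_range = runif(n, 1200, 3900),
    protection = runif(n, 0, 100), n_pas = rpois(n, 5),
    n_kbas = rpois(n, 3), mean_biomass = runif(n, 20, 110),
    stringsAsFactors = FALSE)
  start <- data.frame(reserve_id = 1:n, area_km2 = runif(n, 5, 7000),
                      elev_range = runif(n, 2, 600), protection = 100,
                      mean_biomass = runif(n, 10, 90))
  end <- data.frame(patch_id = 1L, area_km2 = 50, mean_elev = 2000,
                    elev_range = 700, mean_biomass = 80, n_seed_points = 3L,
                    point_x = 0, point_y = 0, protection = 4)
  list(corridor = corridor, start = start, end = end)
}

test_that("feature assembly joins, orders, and inverts as specified", {
  tb <- make_tables(3)
  X <- assemble_features(tb$corridor, tb$start, tb$end)
  spec <- feature_spec()
  expect_equal(dim(X), c(3, sum(spec$include)))
  expect_identical(colnames(X), spec$variable[spec$include])
  # corridor length is negated
  expect_equal(unname(X[, "length_km"]), -tb$corridor$length_km)
  expect_equal(unname(X[, "protection"]), tb$corridor$protection)
  # broken join errors with the corridor id
  bad <- tb$corridor
  bad$start_id[2] <- 999
  expect_error(assemble_features(bad, tb$start, tb$end), "S2_E1")
  # unreachable rows are excluded with a message
  tb$corridor$status[1] <- "unreachable"
  expect_message(X2 <- assemble_features(tb$corridor, tb$start, tb$end),
                 "excluding 1")
  expect_equal(nrow(X2), 2)
})

test_that("collinearity screen drops the designated victim", {
  set.seed(4)
  n <- 100
  a <- rnorm(n)
  X <- cbind(a = a, b = a, c = rnorm(n))  # identical pair
  scr <- screen_collinear(X, 0.7, drop_rank = c(a = 0, b = 0, c = 0))
  expect_equal(colnames(scr$matrix), c("a", "c"))
  expect_equal(scr$report$rho, 1)
  expect_equal(scr$report$dropped, "b")
  # designated drop wins regardless of column order
  scr2 <- screen_collinear(X, 0.7, drop_rank = c(a = 1, b = 0, c = 0))
  expect_equal(colnames(scr2$matrix), c("b", "c"))
  # independent columns survive
  Y <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("x", "y", "z")))
  scr3 <- screen_collinear(Y, 0.7)
  expect_equal(ncol(scr3$matrix), 3)
  expect_equal(nrow(scr3$report), 0)
})

test_that("default spec encodes the documented drop pattern", {
  # n_pas tracking corridor length and end area tracking end elevational
  # range are the designated victims of their collinear pairs
  set.seed(9)
  n <- 200
  tb <- make_tables(n, seed = 9)
  # force the documented correlation structure
  tb$corridor$n_pas <- round(tb$corridor$length_km / 20 + rnorm(n, 0, 2))
  ends <- data.frame(patch_id = 1:n, area_km2 = runif(n, 5, 6000),
                     mean_elev = 2000, elev_range = NA, mean_biomass = 80,
                     n_seed_points = 1L, point_x = 0, point_y = 0,
                     protection = runif(n, 0, 100))
  ends$elev_range <- ends$area_km2 / 5 + rnorm(n, 0, 100)
  tb$corridor$patch_id <- 1:n
  X <- assemble_features(tb$corridor, tb$start, ends)
  scr <- screen_collinear(X, 0.7)
  expect_true("n_pas" %in% scr$report$dropped)
  expect_true("end_area" %in% scr$report$dropped)
  expect_true(all(c("length_km", "end_elev_range") %in%
                    colnames(scr$matrix)))
})

test_that("standardization yields exact z-scores with the n-1 divisor", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  Z <- standardize_features(X)
  expect_equal(unname(Z[, "a"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(Z))), 1e-10)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1))
  # standardizing twice changes the values by nothing
  Z2 <- standardize_features(Z)
  expect_equal(as.vector(Z2), as.vector(Z), tolerance = 1e-12)
  expect_error(standardize_features(cbind(a = c(1, 1, 1), b = 1:3)),
               "a")
})

test_that("PCA recovers known eigenstructure", {
  # two perfectly correlated variables: eigenvalues (2, 0)
  set.seed(2)
  a <- rnorm(50)
  Z <- standardize_features(cbind(x = a, y = 2 * a + 3))
  m <- suppressWarnings(fit_priority_pca(Z, n_components = 3))
  expect_equal(m$eigenvalues, c(2, 0), tolerance = 1e-10)
  expect_equal(m$variance_explained, 1)
  # independent standard columns: eigenvalues near 1
  Zi <- standardize_features(matrix(rnorm(5000 * 4), 5000, 4,
                                    dimnames = list(NULL, letters[1:4])))
  mi <- fit_priority_pca(Zi)
  expect_true(all(abs(mi$eigenvalues - 1) < 0.1))
  # loadings are orthonormal
  G <- t(mi$loadings) %*% mi$loadings
  expect_equal(unname(G), diag(4), tolerance = 1e-8)
  # eigenvalues are non-increasing
  expect_true(all(diff(mi$eigenvalues) <= 1e-12))
})

test_that("priority index is the distance from the origin in PC space", {
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(sprintf("c%d", 1:40), letters[1:5]))
  Z <- standardize_features(X)
  m <- fit_priority_pca(Z)
  sc <- priority_scores(m, Z)
  # Pythagoras on the score columns
  expect_equal(sc$index, sqrt(sc$pc1^2 + sc$pc2^2 + sc$pc3^2))
  # eigen-identity: sum of squared indices = (n-1) * sum of top-3 eigenvalues
  expect_equal(sum(sc$index^2),
               (nrow(Z) - 1) * sum(m$eigenvalues[1:3]),
               tolerance = 1e-6)
  # a corridor at the feature-space mean has index 0
  X0 <- rbind(X, colMeans(X))
  rownames(X0) <- c(rownames(X), "at_mean")
  Z0 <- standardize_features(X0)
  sc0 <- priority_scores(fit_priority_pca(Z0), Z0)
  expect_lt(sc0$index[41], 1e-10)
  # constructed scores (3, 4, 0) give index 5
  expect_equal(sqrt(sum(c(3, 4, 0)^2)), 5)
})

test_that("the index is invariant to sign flips and rotations of the loadings", {
  set.seed(16)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, letters[1:4]))
  Z <- standardize_features(X)
  m <- fit_priority_pca(Z)
  base <- priority_scores(m, Z)$index
  # flip the sign of each retained loading column in turn
  for (j in 1:3) {
    mf <- m
    mf$loadings[, j] <- -mf$loadings[, j]
    expect_equal(priority_scores(mf, Z)$index, base, tolerance = 1e-12)
  }
  # random rigid rotation within the retained 3-space
  qr3 <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  mr <- m
  mr$loadings[, 1:3] <- m$loadings[, 1:3] %*% qr3
  expect_equal(priority_scores(mr, Z)$index, base, tolerance = 1e-12)
})

test_that("classification follows the <2 / 2-4 / >4 convention", {
  idx <- c(0, 0.21, 1.999, 2, 3, 4, 4.001, 7.11)
  cls <- classify_priority(idx)
  expect_equal(as.character(cls),
               c("low", "low", "low", "medium", "medium", "medium",
                 "high", "high"))
  expect_error(classify_priority(-0.1), "non-negative")
  # class counts partition the corridor set
  set.seed(23)
  idx2 <- abs(rnorm(500, 2, 2))
  expect_equal(sum(table(classify_priority(idx2))), 500)
})
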