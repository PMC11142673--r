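#' Planar raster grids
#'
#' `grid_raster()` wraps a numeric matrix as a planar, axis-aligned raster in
#' metric (projected) coordinates. Row 1 is the top of the grid; the center of
#' cell \code{(r, c)} lies at \code{x = xmin + (c - 0.5) * cellsize},
#' \code{y = ymin + (nrow - r + 0.5) * cellsize}. All layers of a landscape
#' must share the same grid (origin, dimensions, cell size); see
#' [same_grid()].
#'
#' @param values numeric (or integer) matrix of cell values; `NA` is nodata.
#' @param xmin,ymin coordinates of the lower-left corner of the grid (m).
#' @param cellsize cell edge length (m), `> 0`.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 100) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @rdname grid_raster
#' @param r,a,b `grid_raster` objects.
#' @export
raster_extent <- function(r) {
  c(xmin = r$xmin, xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymin = r$ymin, ymax = r$ymin + nrow(r$values) * r$cellsize)
}

#' @rdname grid_raster
#' @export
same_grid <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

stop_if_misaligned <- function(..., what = "rasters") {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!same_grid(rs[[1]], rs[[i]]))
      stop(sprintf("%s are not aligned on a shared grid (layer %d differs)",
                   what, i))
  }
  invisible(TRUE)
}

#' Cell <-> coordinate conversions
#'
#' Cells are indexed row-major (`cell = (row - 1) * ncol + col`), with row 1
#' at the top of the grid.
#'
#' @param r a `grid_raster`.
#' @param cells integer vector of row-major cell indices.
#' @return `cell_centers()` / `cell_xy()` return a two-column matrix of
#'   center coordinates; `xy_cell()` returns cell indices (`NA` outside the
#'   grid).
#' @export
cell_xy <- function(r, cells) {
  nc <- ncol(r$values); nr <- nrow(r$values)
  row <- (cells - 1L) %/% nc + 1L
  col <- (cells - 1L) %% nc + 1L
  cbind(x = r$xmin + (col - 0.5) * r$cellsize,
        y = r$ymin + (nr - row + 0.5) * r$cellsize)
}

#' @rdname cell_xy
#' @export
cell_centers <- function(r) {
  cell_xy(r, seq_len(length(r$values)))
}

#' @rdname cell_xy
#' @param x,y coordinate vectors.
#' @export
xy_cell <- function(r, x, y) {
  nc <- ncol(r$values); nr <- nrow(r$values)
  col <- floor((x - r$xmin) / r$cellsize) + 1L
  row <- nr - floor((y - r$ymin) / r$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  out <- (row - 1L) * nc + col
  out[bad] <- NA_integer_
  as.integer(out)
}

# row-major vector view of the value matrix (matches the C++ layout)
values_rowmajor <- function(r) as.vector(t(r$values))

# write a row-major vector back into matrix form
matrix_from_rowmajor <- function(v, nr, nc) matrix(v, nr, nc, byrow = TRUE)

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text `.asc` round trips preserve grid geometry, nodata cells, and
#' values to full double precision.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @param nodata value used to encode `NA` cells on disk.
#' @return `read_raster()` returns a `grid_raster`; `write_raster()` returns
#'   `path` invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  v <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", ncol(v)),
               sprintf("NROWS %d", nrow(v)),
               sprintf("XLLCORNER %.17g", r$xmin),
               sprintf("YLLCORNER %.17g", r$ymin),
               sprintf("CELLSIZE %.17g", r$cellsize),
               sprintf("NODATA_VALUE %.17g", nodata)), con)
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- toupper(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE",
            "NODATA_VALUE")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: ", path)
  nc <- as.integer(vals[["NCOLS"]]); nr <- as.integer(vals[["NROWS"]])
  body <- scan(path, what = double(), skip = 6, quiet = TRUE)
  if (length(body) != nr * nc) stop("ASCII grid body has wrong length: ", path)
  m <- matrix(body, nr, nc, byrow = TRUE)
  m[m == vals[["NODATA_VALUE"]]] <- NA_real_
  grid_raster(m, xmin = vals[["XLLCORNER"]], ymin = vals[["YLLCORNER"]],
              cellsize = vals[["CELLSIZE"]])
}

#' Majority-rule resampling of a categorical raster
#'
#' Aggregates a fine-resolution categorical raster to a coarser grid whose
#' cell size is an integer multiple of the input's. Each coarse cell takes the
#' modal class of its constituent fine cells; ties are broken by the lowest
#' class code. The output grid keeps the input origin.
#'
#' @param landcover a categorical `grid_raster`.
#' @param target_cell target cell size (m); must be an integer multiple of
#'   the input cell size, and the grid dimensions must be divisible by the
#'   resampling factor.
#' @return A `grid_raster` at `target_cell` resolution.
#' @export
resample_categorical <- function(landcover, target_cell) {
  cs <- landcover$cellsize
  f <- target_cell / cs
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop(sprintf("target cell size (%g) is not an integer multiple of the input cell size (%g)",
                 target_cell, cs))
  f <- as.integer(round(f))
  v <- landcover$values
  if (nrow(v) %% f != 0 || ncol(v) %% f != 0)
    stop("grid dimensions are not divisible by the resampling factor")
  if (f == 1L) return(landcover)
  nrC <- nrow(v) %/% f; ncC <- ncol(v) %/% f
  # column-major reshape: dims (f, nrC, f, ncC) index (i, R, j, C) maps to
  # fine cell (r, c) = ((R-1)f + i, (C-1)f + j)
  a <- array(v, dim = c(f, nrC, f, ncC))
  out <- matrix(NA_real_, nrC, ncC)
  for (R in seq_len(nrC)) {
    for (C in seq_len(ncC)) {
      block <- a[, R, , C]
      ux <- sort(unique(as.vector(block)))
      cnt <- tabulate(match(block, ux))
      out[R, C] <- ux[which.max(cnt)]  # first max = lowest code
    }
  }
  grid_raster(out, xmin = landcover$xmin, ymin = landcover$ymin,
              cellsize = target_cell)
}
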