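#' Conductance lookup tables
#'
#' A conductance lookup maps each land-cover class code to a structural
#' conductance value (the inverse of resistance; 0 = impassable) and flags
#' the classes eligible for the forest-biomass modifier. The default table
#' is an illustrative set for a generalist forest mammal (forest highest,
#' built-up and open water impassable) intended for synthetic landscapes
#' and examples; real applications should supply habitat-specific values
#' calibrated for their focal species.
#'
#' @param table optional data.frame with columns `class_code`,
#'   `conductance`, `is_forest` replacing the default.
#' @return A data.frame of class `conductance_lookup`.
#' @export
conductance_lookup <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      class_code = c(10L, 20L, 30L, 40L, 50L, 60L, 80L, 90L),
      conductance = c(1.0, 0.6, 0.5, 0.4, 0.0, 0.2, 0.0, 0.5),
      is_forest = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  }
  need <- c("class_code", "conductance", "is_forest")
  if (!all(need %in% names(table)))
    stop("lookup needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$conductance)) || any(table$conductance < 0))
    stop("conductance values must be finite and non-negative")
  if (anyDuplicated(table$class_code))
    stop("duplicated class_code in lookup")
  class(table) <- c("conductance_lookup", "data.frame")
  table
}

#' Read / write a conductance lookup as CSV
#'
#' @param path CSV file with columns `class_code`, `conductance`,
#'   `is_forest`.
#' @param lookup a [conductance_lookup()].
#' @export
read_conductance_lookup <- function(path) {
  conductance_lookup(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_conductance_lookup
#' @export
write_conductance_lookup <- function(lookup, path) {
  write.csv(as.data.frame(lookup), path, row.names = FALSE)
  invisible(path)
}

#' Forest-biomass conductance modifier
#'
#' Converts a biomass raster into a multiplicative modifier in `[0, 1]`:
#' values above `cap` (default 100 Mt C) are thresholded to `cap` and all
#' values are divided by `cap`, so 0 marks zero-biomass locations and 1
#' marks locations at or above the cap.
#'
#' @param biomass `grid_raster` of aboveground biomass (Mt C), all values
#'   `>= 0`.
#' @param cap biomass saturation threshold (Mt C).
#' @return A `grid_raster` with values in `[0, 1]`.
#' @export
biomass_modifier <- function(biomass, cap = 100) {
  if (cap <= 0) stop("cap must be positive")
  v <- biomass$values
  bad <- which(!is.na(v) & v < 0)
  if (length(bad) > 0)
    stop(sprintf("negative biomass at cell %d (value %g)", bad[1], v[bad[1]]))
  out <- pmin(v, cap) / cap
  grid_raster(matrix(out, nrow(v), ncol(v)), xmin = biomass$xmin,
              ymin = biomass$ymin, cellsize = biomass$cellsize)
}

#' Build the structural conductance surface
#'
#' Assigns each cell the lookup conductance of its land-cover class;
#' forest-flagged classes are additionally multiplied by the biomass
#' modifier, penalizing low-biomass (degraded) forest. Conductance is not
#' adjusted for topography or climate dissimilarity. The result records its
#' provenance (lookup used, whether the modifier was applied, resampling
#' factor) so the modifier cannot be applied twice.
#'
#' @param landcover categorical `grid_raster`.
#' @param lookup a [conductance_lookup()] covering every class present.
#' @param modifier optional `grid_raster` in `[0, 1]` from
#'   [biomass_modifier()], aligned with `landcover`.
#' @param resample_factor provenance note: aggregation factor applied to
#'   the land cover before this call (1 = native resolution).
#' @return A `grid_raster` of conductances with attribute `provenance`.
#' @export
build_conductance <- function(landcover, lookup = conductance_lookup(),
                              modifier = NULL, resample_factor = 1) {
  lookup <- conductance_lookup(lookup)
  v <- landcover$values
  codes <- sort(unique(as.vector(v[!is.na(v)])))
  missing_codes <- setdiff(codes, lookup$class_code)
  if (length(missing_codes) > 0)
    stop("land-cover class code(s) missing from lookup: ",
         paste(missing_codes, collapse = ", "))
  idx <- match(as.vector(v), lookup$class_code)
  cond <- lookup$conductance[idx]
  if (!is.null(modifier)) {
    stop_if_misaligned(landcover, modifier, what = "conductance inputs")
    mv <- as.vector(modifier$values)
    if (any(mv < 0 | mv > 1, na.rm = TRUE))
      stop("modifier values must lie in [0, 1]")
    forest_cell <- lookup$is_forest[idx]
    cond <- ifelse(!is.na(forest_cell) & forest_cell, cond * mv, cond)
  }
  out <- grid_raster(matrix(cond, nrow(v), ncol(v)), xmin = landcover$xmin,
                     ymin = landcover$ymin, cellsize = landcover$cellsize)
  attr(out, "provenance") <- list(lookup = as.data.frame(lookup),
                                  modifier_applied = !is.null(modifier),
                                  resample_factor = resample_factor)
  class(out) <- c("conductance_surface", class(out))
  out
}
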