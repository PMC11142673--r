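#' Run the full corridor pipeline
#'
#' Executes every stage end to end: synthetic-landscape generation (when a
#' [landscape_config()] is supplied) or ingestion of a prepared landscape,
#' reserve cleaning, start-node and end-patch identification, conductance
#' surface construction (class lookup times the forest-biomass modifier),
#' least-cost corridors from each start node to its `k` nearest end
#' points, corridor and node metrics, the PCA priority index with its
#' three classes, and the class-comparison statistics. A manifest records
#' parameters, seed, and per-stage record counts; the same configuration
#' reproduces every output exactly.
#'
#' @param landscape a [landscape_config()] (the synthetic landscape is
#'   generated) or a ready `synthetic_landscape`-shaped list with aligned
#'   `dem`, `landcover`, `biomass`, `integrity` rasters and `reserves`,
#'   `kbas`, `countries` polygon tables.
#' @param thresholds a [node_thresholds()].
#' @param lookup a [conductance_lookup()].
#' @param connectivity lattice connectivity, 8 (default) or 4.
#' @param k end points paired per start node (default 5).
#' @param half_width corridor buffer half-width in m (default 1000).
#' @param spec a [feature_spec()].
#' @param rho_threshold collinearity screen threshold (default 0.7).
#' @param n_components retained principal components (default 3).
#' @param class_thresholds priority class cuts (default `c(2, 4)`).
#' @param biomass_cap biomass modifier saturation (Mt C, default 100).
#' @param snap_radius endpoint snapping radius in cells (default 5).
#' @param gate_alpha omnibus gate for the pairwise statistics.
#' @param out_dir optional output directory; when given, tables (CSV),
#'   rasters (ASCII grid), vector layers (GeoJSON), and the manifest
#'   (JSON) are written there.
#' @return A list of class `corridor_pipeline` with elements `landscape`,
#'   `reserves_clean`, `start_nodes`, `end_patches`, `end_points`,
#'   `surface`, `corridors`, `corridor_table`, `node_tables`, `priority`,
#'   `stats`, and `manifest`.
#' @export
run_pipeline <- function(landscape = landscape_config(),
                         thresholds = node_thresholds(),
                         lookup = conductance_lookup(), connectivity = 8,
                         k = 5, half_width = 1000, spec = feature_spec(),
                         rho_threshold = 0.7, n_components = 3,
                         class_thresholds = c(2, 4), biomass_cap = 100,
                         snap_radius = 5, gate_alpha = 0.05,
                         out_dir = NULL) {
  if (inherits(landscape, "landscape_config"))
    landscape <- generate_landscape(landscape)
  stop_if_misaligned(landscape$dem, landscape$landcover, landscape$biomass,
                     landscape$integrity, what = "landscape rasters")
  ext <- raster_extent(landscape$dem)

  reserves_clean <- clean_reserves(landscape$reserves, ext)
  start_nodes <- identify_start_nodes(reserves_clean, landscape$dem,
                                      thresholds)
  end_patches <- extract_end_patches(landscape$landcover,
                                     landscape$integrity, landscape$dem,
                                     landscape$biomass, thresholds)
  end_points <- end_point_table(end_patches)

  modifier <- biomass_modifier(landscape$biomass, cap = biomass_cap)
  surface <- build_conductance(landscape$landcover, lookup, modifier)
  graph <- build_graph(surface, connectivity)
  corridors <- batch_corridors(graph, start_nodes, end_points, k = k,
                               snap_radius = snap_radius)

  corridor_table <- corridor_metrics(corridors, landscape$dem,
                                     landscape$biomass, reserves_clean,
                                     landscape$kbas, landscape$countries,
                                     half_width = half_width)
  node_tables <- node_metrics(start_nodes, end_patches, landscape$dem,
                              landscape$biomass, reserves_clean)

  priority <- NULL
  stats_table <- NULL
  ok_rows <- sum(corridor_table$status == "ok")
  if (ok_rows >= 3) {
    priority <- compute_priority(corridor_table, node_tables$start,
                                 node_tables$end, spec = spec,
                                 rho_threshold = rho_threshold,
                                 n_components = n_components,
                                 class_thresholds = class_thresholds)
    cls <- priority$scores$class
    if (nlevels(droplevels(cls)) >= 2) {
      ok_tab <- corridor_table[corridor_table$status == "ok", , drop = FALSE]
      stats_table <- class_comparison(
        ok_tab[c("length_km", "elev_range", "protection", "n_pas",
                 "n_kbas", "mean_biomass")],
        cls, gate_alpha = gate_alpha)
    } else {
      message("all corridors fall in one priority class; no group statistics")
    }
  } else {
    message("fewer than 3 corridors with metrics; priority index skipped")
  }

  manifest <- list(
    package = "climcorridor",
    version = as.character(utils::packageVersion("climcorridor")),
    seed = if (!is.null(landscape$config)) landscape$config$seed else NA,
    parameters = list(
      landscape = if (!is.null(landscape$config))
        unclass(landscape$config) else NULL,
      thresholds = unclass(thresholds), connectivity = connectivity,
      k = k, half_width = half_width, biomass_cap = biomass_cap,
      snap_radius = snap_radius, rho_threshold = rho_threshold,
      n_components = n_components, class_thresholds = class_thresholds,
      lookup = as.data.frame(lookup)),
    counts = list(
      n_reserves_raw = nrow(landscape$reserves),
      n_reserves_clean = nrow(reserves_clean),
      n_start_nodes = nrow(start_nodes),
      n_end_patches = length(end_patches),
      n_end_points = nrow(end_points),
      n_paths = nrow(corridors$table),
      n_paths_reachable = sum(corridors$table$status == "ok"),
      n_class = if (!is.null(priority))
        as.list(table(priority$scores$class)) else NULL),
    variance_explained = if (!is.null(priority))
      priority$model$variance_explained else NULL)

  result <- structure(list(landscape = landscape,
                           reserves_clean = reserves_clean,
                           start_nodes = start_nodes,
                           end_patches = end_patches,
                           end_points = end_points, surface = surface,
                           corridors = corridors,
                           corridor_table = corridor_table,
                           node_tables = node_tables, priority = priority,
                           stats = stats_table, manifest = manifest),
                      class = "corridor_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.corridor_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<corridor_pipeline>\n")
  cat(sprintf("  reserves: %d raw -> %d clean; start nodes: %d; end patches: %d (%d end points)\n",
              cnt$n_reserves_raw, cnt$n_reserves_clean, cnt$n_start_nodes,
              cnt$n_end_patches, cnt$n_end_points))
  cat(sprintf("  corridors: %d traced, %d reachable\n", cnt$n_paths,
              cnt$n_paths_reachable))
  if (!is.null(x$priority))
    cat(sprintf("  priority: %s (first %d PCs explain %.1f%% of variance)\n",
                paste(sprintf("%s=%d", names(cnt$n_class),
                              unlist(cnt$n_class)), collapse = " "),
                x$priority$model$n_components,
                100 * x$manifest$variance_explained))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Tables as CSV, rasters as ESRI ASCII grids, corridor polylines and
#' polygon layers as GeoJSON, and the run manifest as JSON.
#'
#' @param result a `corridor_pipeline` object.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write.csv(result$corridor_table, fp("corridor_metrics.csv"),
            row.names = FALSE)
  sn <- result$start_nodes
  write.csv(sn[setdiff(names(sn), "geometry")], fp("start_nodes.csv"),
            row.names = FALSE)
  write.csv(end_patch_table(result$end_patches), fp("end_patches.csv"),
            row.names = FALSE)
  write.csv(result$end_points, fp("end_points.csv"), row.names = FALSE)
  if (!is.null(result$priority)) {
    write.csv(result$priority$scores, fp("priority.csv"), row.names = FALSE)
    write.csv(result$priority$screen_report, fp("collinearity_screen.csv"),
              row.names = FALSE)
    ld <- result$priority$model$loadings
    write.csv(data.frame(variable = rownames(ld), ld),
              fp("pca_loadings.csv"), row.names = FALSE)
  }
  if (!is.null(result$stats))
    write.csv(result$stats, fp("class_stats.csv"), row.names = FALSE)
  write_raster(result$landscape$dem, fp("dem.asc"))
  write_raster(result$surface, fp("conductance.asc"))
  write_paths_geojson(result$corridors, fp("corridors.geojson"))
  write_vector(result$reserves_clean, fp("reserves_clean.geojson"))
  invisible(out_dir)
}
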