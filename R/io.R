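#' Read and write polygon tables as GeoJSON
#'
#' Polygon tables (data.frames with a `geometry` list-column of coordinate
#' rings) round-trip through GeoJSON FeatureCollections. On write, rings
#' are closed per the GeoJSON convention; on read, the closing vertex is
#' dropped again. Geometries are validated: self-intersecting rings are
#' repaired by their convex hull (logged); empty or degenerate rings are an
#' error listing the offending feature ids.
#'
#' @param table polygon table (attributes + `geometry` list-column).
#' @param path file path.
#' @return `read_vector()` returns the polygon table; `write_vector()`
#'   returns `path` invisibly.
#' @export
write_vector <- function(table, path) {
  if (!"geometry" %in% names(table)) stop("table has no `geometry` column")
  props <- table[setdiff(names(table), "geometry")]
  features <- lapply(seq_len(nrow(table)), function(i) {
    g <- table$geometry[[i]]
    rings <- if (is.list(g)) g else list(g)
    coords <- lapply(rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    geom <- if (length(coords) == 1) {
      list(type = "Polygon", coordinates = coords)
    } else {
      list(type = "MultiPolygon", coordinates = lapply(coords, list))
    }
    list(type = "Feature",
         properties = as.list(props[i, , drop = FALSE]),
         geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# does the ring self-intersect (non-adjacent edge pair crossing)?
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  seg <- function(i) list(a = ring[i, ], b = ring[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  intersects <- function(p, q) {
    d1 <- cross(p$a, p$b, q$a); d2 <- cross(p$a, p$b, q$b)
    d3 <- cross(q$a, q$b, p$a); d4 <- cross(q$a, q$b, p$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closure
      if (intersects(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# validate/repair geometries; convex-hull repair for self-intersections
validate_geometries <- function(table, ids = table$id) {
  bad <- character(0)
  for (i in seq_len(nrow(table))) {
    g <- table$geometry[[i]]
    rings <- if (is.list(g)) g else list(g)
    fixed <- lapply(rings, function(r) {
      if (is.null(r) || nrow(r) < 3) return(NULL)
      if (ring_self_intersects(r)) {
        message(sprintf("feature %s: self-intersecting ring repaired by convex hull",
                        ids[i]))
        r <- r[rev(grDevices::chull(r)), , drop = FALSE]
      }
      if (nrow(r) < 3 || polygon_area(r) <= 0) return(NULL)
      r
    })
    fixed <- Filter(Negate(is.null), fixed)
    if (length(fixed) == 0) {
      bad <- c(bad, as.character(ids[i]))
    } else {
      table$geometry[[i]] <- if (length(fixed) == 1) fixed[[1]] else fixed
    }
  }
  if (length(bad) > 0)
    stop("invalid geometry for feature(s): ", paste(bad, collapse = ", "))
  table
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- fc$features
  props <- lapply(feats, function(f) {
    lapply(f$properties, function(p) if (is.null(p)) NA else p)
  })
  prop_names <- unique(unlist(lapply(props, names)))
  cols <- lapply(prop_names, function(nm) {
    unlist(lapply(props, function(p) if (is.null(p[[nm]])) NA else p[[nm]]))
  })
  out <- as.data.frame(setNames(cols, prop_names),
                       stringsAsFactors = FALSE)
  parse_ring <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    m[-nrow(m), , drop = FALSE]  # drop the closing vertex
  }
  out$geometry <- lapply(feats, function(f) {
    geom <- f$geometry
    if (geom$type == "Polygon") {
      parse_ring(geom$coordinates[[1]])
    } else if (geom$type == "MultiPolygon") {
      lapply(geom$coordinates, function(poly) parse_ring(poly[[1]]))
    } else {
      stop("unsupported geometry type: ", geom$type)
    }
  })
  validate_geometries(out)
}

#' Write corridor polylines as GeoJSON LineStrings
#'
#' @param corridors result of [batch_corridors()].
#' @param path file path.
#' @export
write_paths_geojson <- function(corridors, path) {
  tab <- corridors$table
  features <- lapply(seq_len(nrow(tab)), function(i) {
    cid <- tab$corridor_id[i]
    p <- corridors$paths[[cid]]
    coords <- if (is.null(p)) list() else
      lapply(seq_len(nrow(p$line)), function(k) {
        c(p$line[k, 1], p$line[k, 2])
      })
    list(type = "Feature",
         properties = list(corridor_id = cid, start_id = tab$start_id[i],
                           end_point_id = tab$end_point_id[i],
                           accumulated_cost = tab$accumulated_cost[i],
                           status = tab$status[i]),
         geometry = list(type = "LineString", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
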