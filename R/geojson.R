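# GeoJSON (RFC 7946) reading/writing for the urban environment. Coordinates
# are planar metres in a local frame, declared via a top-level "crs_note"
# property rather than a geographic CRS.

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", geometry = geometry, properties = properties)
}

#' Serialise an environment to GeoJSON files
#'
#' Writes `zones.geojson` (zone polygons with deprivation quintiles),
#' `landuse.geojson` (all sites, including homes, schools and shops, as
#' points with a `kind` and `area`) and `roads.geojson` (one LineString per
#' road edge with its `walkability`) into `dir`. The files can be read back
#' with [load_environment()].
#'
#' @param env `pa_environment`.
#' @param dir output directory (created if missing).
#' @return invisible character vector of the three file paths.
#' @export
env_to_geojson <- function(env, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  crs_note <- "local planar metres, origin at SW corner"

  zf <- lapply(seq_len(nrow(env$zones)), function(k) {
    ring <- env$zone_polys[[k]]
    ring <- rbind(ring, ring[1, ])                      # close the ring
    geojson_feature(list(type = "Polygon", coordinates = list(ring)),
                    list(id = env$zones$id[k],
                         simd_quintile = env$zones$simd_quintile[k]))
  })
  lf <- lapply(seq_len(nrow(env$sites)), function(k) {
    geojson_feature(list(type = "Point",
                         coordinates = c(env$sites$x[k], env$sites$y[k])),
                    list(id = env$sites$id[k], kind = env$sites$kind[k],
                         area = env$sites$area[k]))
  })
  rf <- lapply(seq_len(nrow(env$edges)), function(k) {
    a <- env$edges$from[k]; b <- env$edges$to[k]
    coords <- rbind(c(env$nodes$x[a], env$nodes$y[a]),
                    c(env$nodes$x[b], env$nodes$y[b]))
    geojson_feature(list(type = "LineString", coordinates = coords),
                    list(id = paste0("road_", k),
                         walkability = env$edges$walkability[k]))
  })

  paths <- file.path(dir, c("zones.geojson", "landuse.geojson", "roads.geojson"))
  feats <- list(zf, lf, rf)
  for (i in 1:3) {
    fc <- list(type = "FeatureCollection", crs_note = crs_note,
               features = feats[[i]])
    jsonlite::write_json(fc, paths[i], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

get_prop <- function(feat, name, file, required = TRUE) {
  v <- feat$properties[[name]]
  if (is.null(v) && required) {
    stop_config("feature '%s' in %s is missing required property '%s'",
                feat$properties$id %||% "<unnamed>", file, name)
  }
  v
}

coords_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Load an urban environment from GeoJSON layers
#'
#' Expects three FeatureCollections in a local planar-metre frame:
#' zone polygons with a `simd_quintile` property, land-use point or polygon
#' features with a `kind` (and an `area` where the geometry is a point), and
#' road LineStrings with a `walkability` property. The loaded environment is
#' run through the same invariant suite as the synthetic generator.
#'
#' @param zone_file,landuse_file,roads_file file paths.
#' @return `pa_environment`.
#' @export
load_environment <- function(zone_file, landuse_file, roads_file) {
  zj <- jsonlite::fromJSON(zone_file, simplifyVector = FALSE)
  lj <- jsonlite::fromJSON(landuse_file, simplifyVector = FALSE)
  rj <- jsonlite::fromJSON(roads_file, simplifyVector = FALSE)
  for (x in list(zj, lj, rj)) {
    if (!identical(x$type, "FeatureCollection")) {
      stop_config("all inputs must be GeoJSON FeatureCollections")
    }
  }

  # zones
  zone_polys <- list(); qs <- integer(0); ids <- character(0)
  for (feat in zj$features) {
    q <- get_prop(feat, "simd_quintile", zone_file)
    if (!q %in% 1:5) stop_config("simd_quintile must be in 1..5")
    ring <- coords_matrix(feat$geometry$coordinates[[1]])
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), ]
    zone_polys[[length(zone_polys) + 1]] <- ring
    qs <- c(qs, as.integer(q))
    ids <- c(ids, feat$properties$id %||% paste0("DZ", length(ids) + 1))
  }
  cents <- t(vapply(zone_polys, polygon_centroid, numeric(2)))
  zones <- data.frame(id = ids, simd_quintile = qs, s = SIMD_S[qs],
                      area = vapply(zone_polys, polygon_area, 0),
                      cx = cents[, 1], cy = cents[, 2],
                      stringsAsFactors = FALSE)

  # roads -> node/edge tables (vertices keyed on rounded coordinates)
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  node_key <- character(0); nx <- ny <- numeric(0)
  from <- to <- integer(0); elen <- ewalk <- numeric(0)
  node_of <- function(x, y) {
    k <- key(x, y)
    i <- match(k, node_key)
    if (is.na(i)) {
      node_key <<- c(node_key, k); nx <<- c(nx, x); ny <<- c(ny, y)
      i <- length(node_key)
    }
    i
  }
  for (feat in rj$features) {
    w <- get_prop(feat, "walkability", roads_file)
    cm <- coords_matrix(feat$geometry$coordinates)
    for (i in seq_len(nrow(cm) - 1)) {
      a <- node_of(cm[i, 1], cm[i, 2]); b <- node_of(cm[i + 1, 1], cm[i + 1, 2])
      from <- c(from, a); to <- c(to, b)
      elen <- c(elen, sqrt(sum((cm[i, ] - cm[i + 1, ])^2)))
      ewalk <- c(ewalk, as.numeric(w))
    }
  }
  nodes <- data.frame(x = nx, y = ny)
  edges <- data.frame(from = from, to = to, length = elen, walkability = ewalk)

  # land use
  srows <- lapply(seq_along(lj$features), function(k) {
    feat <- lj$features[[k]]
    kind <- get_prop(feat, "kind", landuse_file)
    if (identical(feat$geometry$type, "Point")) {
      x <- feat$geometry$coordinates[[1]]; y <- feat$geometry$coordinates[[2]]
      area <- as.numeric(get_prop(feat, "area", landuse_file))
    } else {
      ring <- coords_matrix(feat$geometry$coordinates[[1]])
      if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), ]
      cen <- polygon_centroid(ring)
      x <- cen[1]; y <- cen[2]
      area <- feat$properties$area %||% polygon_area(ring)
    }
    data.frame(id = feat$properties$id %||% paste0(kind, "_", k), kind = kind,
               x = x, y = y, area = area, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, srows)
  sites$large <- as.integer(sites$area > 10000)
  sites$node <- vapply(seq_len(nrow(sites)), function(i) {
    which.min((nodes$x - sites$x[i])^2 + (nodes$y - sites$y[i])^2)
  }, 0L)
  sites$zone <- vapply(seq_len(nrow(sites)), function(i) {
    z <- which_zone(sites$x[i], sites$y[i], zone_polys)
    if (is.na(z)) {
      # boundary points miss every polygon under strict ray casting;
      # assign the zone with the nearest centroid
      z <- which.min((cents[, 1] - sites$x[i])^2 +
                     (cents[, 2] - sites$y[i])^2)
    }
    as.integer(z)
  }, 0L)
  sites <- sites[, c("id", "kind", "x", "y", "area", "large", "zone", "node")]

  allx <- unlist(lapply(zone_polys, function(p) p[, 1]))
  ally <- unlist(lapply(zone_polys, function(p) p[, 2]))
  env <- build_environment(zones, zone_polys, sites, nodes, edges,
                           bbox = c(min(allx), min(ally), max(allx), max(ally)))
  validate_environment(env)
  env
}
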