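# Urban environment: data zones with deprivation, land-use sites, homes,
# schools with catchments, shops and a walkable road network. Coordinates are
# planar metres with the origin at the south-west corner of the study area.

SIMD_S <- c(1, 0.9, 0.8, 0.7, 0.6)   # quintile 1 (least deprived) -> 5 (most)
OUTDOOR_KINDS <- c("garden", "sports_field", "park", "amenity")
FSA_KINDS <- c("leisure_centre", "sports_field", "school")

#' Specification of a synthetic city
#'
#' Describes a rectangular study area divided into a grid of equally sized data
#' zones, with counts of land-use sites placed uniformly at random and snapped
#' to a regular street grid. The deprivation layout assigns a quintile to each
#' zone: `"random"` draws quintiles independently, `"gradient"` makes them
#' monotone along the x axis, `"clustered"` bins zones by distance from a
#' randomly chosen focal zone.
#'
#' @param nx,ny grid dimensions in zones (default 6 x 5, a 2.4 x 2.0 km
#'   area giving school commutes of realistic length).
#' @param zone_size side length of a square zone, metres (400).
#' @param homes_per_zone residential buildings per zone (17).
#' @param schools,parks,sports_fields,gardens,amenities,leisure_centres,shops
#'   site counts.
#' @param deprivation layout mode, one of `"random"`, `"gradient"`,
#'   `"clustered"`.
#' @param road_spacing street-grid node spacing, metres (200).
#' @param park_area optional fixed area for every park (m^2); by default park
#'   areas are drawn log-normally so that some exceed the 10,000 m^2
#'   large-site threshold.
#' @return object of class `city_spec`.
#' @export
city_spec <- function(nx = 6, ny = 5, zone_size = 400, homes_per_zone = 17,
                      schools = 2, parks = 6, sports_fields = 6, gardens = 40,
                      amenities = 20, leisure_centres = 3, shops = 18,
                      deprivation = c("random", "gradient", "clustered"),
                      road_spacing = 200, park_area = NULL) {
  if (nx <= 0 || ny <= 0) stop_config("zone grid dimensions must be positive")
  if (homes_per_zone <= 0) stop_config("homes_per_zone must be positive")
  counts <- c(schools = schools, parks = parks, sports_fields = sports_fields,
              gardens = gardens, amenities = amenities,
              leisure_centres = leisure_centres, shops = shops)
  if (any(counts < 0) || schools < 1) {
    stop_config("site counts must be non-negative and schools >= 1")
  }
  spec <- list(nx = nx, ny = ny, zone_size = zone_size,
               homes_per_zone = homes_per_zone, schools = schools,
               parks = parks, sports_fields = sports_fields,
               gardens = gardens, amenities = amenities,
               leisure_centres = leisure_centres, shops = shops,
               deprivation = match.arg(deprivation),
               road_spacing = road_spacing, park_area = park_area)
  class(spec) <- "city_spec"
  spec
}

draw_site_area <- function(kind, n, park_area = NULL) {
  switch(kind,
    park = if (!is.null(park_area)) rep(park_area, n) else
      exp(rnorm(n, log(9000), 0.7)),
    sports_field = runif(n, 4000, 9000),
    garden = runif(n, 300, 1500),
    amenity = runif(n, 1000, 6000),
    leisure_centre = rep(2000, n),
    shop = rep(300, n),
    school = rep(8000, n),
    home = rep(150, n)
  )
}

assign_quintiles <- function(spec) {
  nz <- spec$nx * spec$ny
  cols <- rep(seq_len(spec$nx), times = spec$ny)   # zone column index
  rows <- rep(seq_len(spec$ny), each = spec$nx)
  switch(spec$deprivation,
    random = sample(1:5, nz, replace = TRUE),
    gradient = as.integer(cut(cols, breaks = 5, labels = FALSE)),
    clustered = {
      focal <- sample.int(nz, 1)
      d <- sqrt((cols - cols[focal])^2 + (rows - rows[focal])^2)
      as.integer(cut(rank(d, ties.method = "first"), breaks = 5,
                     labels = FALSE))
    }
  )
}

#' Generate a synthetic urban environment
#'
#' Builds a complete study area from a [city_spec()]: square data zones with a
#' deprivation quintile and its multiplier on outdoor play
#' (quintile 1 to 5 mapped to s = 1, 0.9, 0.8, 0.7, 0.6), homes, schools with
#' one catchment school per zone, shops and outdoor sites, and a connected
#' street grid whose per-edge walkability is Beta-distributed with a
#' deprivation-correlated mean. Deterministic for a fixed `(spec, seed)`.
#'
#' @param spec a [city_spec()].
#' @param seed integer seed.
#' @return object of class `pa_environment`.
#' @export
synthetic_city <- function(spec = city_spec(), seed = 1) {
  if (!inherits(spec, "city_spec")) spec <- do.call(city_spec, spec)
  force(seed)
  set.seed(seed)
  W <- spec$nx * spec$zone_size
  H <- spec$ny * spec$zone_size

  # zones: row-major grid of squares
  nz <- spec$nx * spec$ny
  zone_polys <- vector("list", nz)
  cx <- cy <- numeric(nz)
  k <- 0
  for (j in seq_len(spec$ny)) {
    for (i in seq_len(spec$nx)) {
      k <- k + 1
      x0 <- (i - 1) * spec$zone_size; y0 <- (j - 1) * spec$zone_size
      zone_polys[[k]] <- cbind(c(x0, x0 + spec$zone_size, x0 + spec$zone_size, x0),
                               c(y0, y0, y0 + spec$zone_size, y0 + spec$zone_size))
      cx[k] <- x0 + spec$zone_size / 2; cy[k] <- y0 + spec$zone_size / 2
    }
  }
  quintile <- assign_quintiles(spec)
  zones <- data.frame(id = paste0("DZ", seq_len(nz)), simd_quintile = quintile,
                      s = SIMD_S[quintile],
                      area = vapply(zone_polys, polygon_area, 0),
                      cx = cx, cy = cy, stringsAsFactors = FALSE)

  # street grid
  xs <- seq(0, W, by = spec$road_spacing)
  ys <- seq(0, H, by = spec$road_spacing)
  nodes <- expand.grid(x = xs, y = ys)
  nnx <- length(xs); nny <- length(ys)
  node_id <- function(i, j) (j - 1L) * nnx + i
  from <- to <- integer(0)
  for (j in seq_len(nny)) for (i in seq_len(nnx)) {
    if (i < nnx) { from <- c(from, node_id(i, j)); to <- c(to, node_id(i + 1L, j)) }
    if (j < nny) { from <- c(from, node_id(i, j)); to <- c(to, node_id(i, j + 1L)) }
  }
  len <- sqrt((nodes$x[from] - nodes$x[to])^2 + (nodes$y[from] - nodes$y[to])^2)
  midx <- (nodes$x[from] + nodes$x[to]) / 2
  midy <- (nodes$y[from] + nodes$y[to]) / 2
  ezone <- pmin(pmax(floor(midx / spec$zone_size), 0), spec$nx - 1) + 1 +
    pmin(pmax(floor(midy / spec$zone_size), 0), spec$ny - 1) * spec$nx
  wmean <- clamp(0.75 - 0.05 * (zones$simd_quintile[ezone] - 1), 0.05, 0.95)
  conc <- 12
  walkability <- rbeta(length(from), wmean * conc, (1 - wmean) * conc)
  edges <- data.frame(from = from, to = to, length = len,
                      walkability = walkability)

  # sites: homes per zone, other kinds uniform over the study area
  site_rows <- list()
  add_sites <- function(kind, n, px, py) {
    if (n == 0) return(NULL)
    data.frame(kind = kind, x = px, y = py,
               area = draw_site_area(kind, n, spec$park_area),
               stringsAsFactors = FALSE)
  }
  for (z in seq_len(nz)) {
    p <- zone_polys[[z]]
    px <- runif(spec$homes_per_zone, min(p[, 1]), max(p[, 1]))
    py <- runif(spec$homes_per_zone, min(p[, 2]), max(p[, 2]))
    site_rows[[length(site_rows) + 1]] <- add_sites("home", spec$homes_per_zone, px, py)
  }
  other <- c(school = spec$schools, park = spec$parks,
             sports_field = spec$sports_fields, garden = spec$gardens,
             amenity = spec$amenities, leisure_centre = spec$leisure_centres,
             shop = spec$shops)
  for (kind in names(other)) {
    n <- other[[kind]]
    if (n > 0) {
      site_rows[[length(site_rows) + 1]] <-
        add_sites(kind, n, runif(n, 0, W), runif(n, 0, H))
    }
  }
  sites <- do.call(rbind, site_rows)
  if (sum(sites$area[sites$kind != "home"]) > 0.6 * W * H) {
    stop_config("requested sites exceed the area capacity of the city")
  }
  sites$id <- paste0(sites$kind, "_", stats::ave(seq_len(nrow(sites)),
                                                 sites$kind, FUN = seq_along))
  sites$large <- as.integer(sites$area > 10000)
  # snap to the nearest street node for network access; the site itself
  # keeps its generated position (and therefore its generating zone)
  sites$node <- vapply(seq_len(nrow(sites)), function(i) {
    which.min((nodes$x - sites$x[i])^2 + (nodes$y - sites$y[i])^2)
  }, 0L)
  sites$zone <- vapply(seq_len(nrow(sites)), function(i) {
    zx <- pmin(pmax(floor(sites$x[i] / spec$zone_size), 0), spec$nx - 1)
    zy <- pmin(pmax(floor(sites$y[i] / spec$zone_size), 0), spec$ny - 1)
    as.integer(zx + 1 + zy * spec$nx)
  }, 0L)
  sites <- sites[, c("id", "kind", "x", "y", "area", "large", "zone", "node")]

  env <- build_environment(zones, zone_polys, sites, nodes, edges,
                           bbox = c(0, 0, W, H))
  validate_environment(env)
  env
}

# assemble graph + catchments and class the object
build_environment <- function(zones, zone_polys, sites, nodes, edges, bbox) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nodes))))
  igraph::E(g)$weight <- edges$length
  igraph::E(g)$walkability <- edges$walkability

  school_idx <- which(sites$kind == "school")
  if (length(school_idx) == 0) stop_config("environment has no school")
  catch <- vapply(seq_len(nrow(zones)), function(z) {
    d <- (sites$x[school_idx] - zones$cx[z])^2 +
         (sites$y[school_idx] - zones$cy[z])^2
    school_idx[which.min(d)]
  }, 0L)

  env <- list(zones = zones, zone_polys = zone_polys, sites = sites,
              nodes = nodes, edges = edges, graph = g,
              catchments = data.frame(zone = seq_len(nrow(zones)),
                                      school = catch),
              bbox = bbox)
  class(env) <- "pa_environment"
  env
}

#' Validate an urban environment against the full invariant suite
#'
#' Checks deprivation quintiles and their multipliers, site areas and the
#' large-site flag (area > 10,000 m^2), containment of every site in exactly
#' one zone (zone polygons must not overlap, checked by random-point
#' sampling), connectivity of the road network over all site access nodes,
#' agreement of edge lengths with node coordinates, at least one home per
#' zone, and a reachable catchment school for every zone.
#'
#' @param env `pa_environment`.
#' @param n_partition_samples random points used for the overlap check.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_environment <- function(env, n_partition_samples = 200) {
  z <- env$zones
  if (!all(z$simd_quintile %in% 1:5)) stop_config("quintiles must be in 1..5")
  if (!isTRUE(all.equal(z$s, SIMD_S[z$simd_quintile]))) {
    stop_config("deprivation multipliers must follow the 1, 0.9, 0.8, 0.7, 0.6 mapping")
  }
  s <- env$sites
  if (any(s$area < 0)) stop_config("site areas must be non-negative")
  if (!all(s$large == as.integer(s$area > 10000))) {
    stop_config("large-site flag must equal area > 10,000 m^2")
  }
  if (any(is.na(s$zone))) stop_config("every site must lie inside a zone")
  # overlap check: random points must fall in at most one zone polygon
  px <- runif(n_partition_samples, env$bbox[1], env$bbox[3])
  py <- runif(n_partition_samples, env$bbox[2], env$bbox[4])
  for (i in seq_len(n_partition_samples)) {
    hits <- sum(vapply(env$zone_polys,
                       function(p) point_in_polygon(px[i], py[i], p), FALSE))
    if (hits > 1) stop_config("zone polygons overlap")
  }
  # edge lengths equal euclidean node distance
  e <- env$edges
  elen <- sqrt((env$nodes$x[e$from] - env$nodes$x[e$to])^2 +
               (env$nodes$y[e$from] - env$nodes$y[e$to])^2)
  if (any(abs(elen - e$length) > 1e-6 + 1e-9 * elen)) {
    stop_config("edge lengths must equal euclidean node distances")
  }
  if (any(e$walkability < 0 | e$walkability > 1)) {
    stop_config("walkability scores must lie in [0, 1]")
  }
  # connectivity over site access nodes
  comp <- igraph::components(env$graph)$membership
  site_comp <- comp[s$node]
  if (length(unique(site_comp)) > 1) {
    stop_config("road network is disconnected over site access nodes")
  }
  # homes and catchments
  homes_per_zone <- table(factor(s$zone[s$kind == "home"],
                                 levels = seq_len(nrow(z))))
  if (any(homes_per_zone == 0)) {
    bad <- z$id[which(homes_per_zone == 0)[1]]
    stop_config("zone %s contains no home", bad)
  }
  if (nrow(env$catchments) != nrow(z) ||
      anyNA(env$catchments$school)) {
    stop_config("every zone must map to exactly one catchment school")
  }
  invisible(TRUE)
}

#' Shortest route between two sites on the road network
#'
#' Edge lengths are the routing weight; the returned walkability is the
#' length-weighted mean of edge walkability along the optimal path.
#'
#' @param env `pa_environment`.
#' @param origin,dest site ids (character) or row indices into `env$sites`.
#' @return list with `path` (node indices), `length` (m) and
#'   `mean_walkability`; an identical origin and destination give length 0 and
#'   an empty path.
#' @export
shortest_route <- function(env, origin, dest) {
  oi <- if (is.character(origin)) match(origin, env$sites$id) else origin
  di <- if (is.character(dest)) match(dest, env$sites$id) else dest
  if (is.na(oi) || is.na(di)) stop_config("unknown site")
  o <- env$sites$node[oi]; d <- env$sites$node[di]
  if (o == d) {
    return(list(path = integer(0), length = 0, mean_walkability = NA_real_))
  }
  sp <- igraph::shortest_paths(env$graph, from = o, to = d,
                               weights = igraph::E(env$graph)$weight,
                               output = "both")
  if (length(sp$vpath[[1]]) == 0) stop_config("sites are not connected")
  ep <- sp$epath[[1]]
  lens <- igraph::edge_attr(env$graph, "weight", ep)
  walks <- igraph::edge_attr(env$graph, "walkability", ep)
  list(path = as.integer(igraph::as_ids(sp$vpath[[1]])),
       length = sum(lens),
       mean_walkability = sum(lens * walks) / sum(lens))
}

#' @export
print.pa_environment <- function(x, ...) {
  cat(sprintf("Urban environment: %d zones over %.1f km^2, %d sites, %d road nodes / %d edges\n",
              nrow(x$zones),
              (x$bbox[3] - x$bbox[1]) * (x$bbox[4] - x$bbox[2]) / 1e6,
              nrow(x$sites), nrow(x$nodes), nrow(x$edges)))
  tab <- table(x$sites$kind)
  cat("  sites:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  deprivation quintiles:",
      paste(sprintf("q%d:%d", 1:5,
                    tabulate(x$zones$simd_quintile, 5)), collapse = " "), "\n")
  invisible(x)
}
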