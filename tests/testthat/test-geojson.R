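write_fixture_city <- function(dir, drop_quintile = FALSE,
                               zero_home_zone = FALSE) {
  # two 500 m zones side by side with a 3-node road spine
  mkring <- function(x0) rbind(c(x0, 0), c(x0 + 500, 0), c(x0 + 500, 500),
                               c(x0, 500), c(x0, 0))
  zones <- lapply(1:2, function(z) {
    props <- list(id = paste0("Z", z), simd_quintile = c(1, 5)[z])
    if (drop_quintile && z == 2) props$simd_quintile <- NULL
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(mkring((z - 1) * 500))),
         properties = props)
  })
  roads <- list(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = rbind(c(50, 250), c(500, 250),
                                        c(950, 250))),
    properties = list(id = "r1", walkability = 0.8)))
  pts <- list(
    list(id = "h1", kind = "home", x = 50, y = 250, area = 100),
    list(id = "h2", kind = "home", x = 950, y = 250, area = 100),
    list(id = "sch", kind = "school", x = 500, y = 250, area = 8000),
    list(id = "p1", kind = "park", x = 950, y = 250, area = 15000),
    list(id = "shop1", kind = "shop", x = 500, y = 250, area = 200))
  if (zero_home_zone) pts <- Filter(function(p) p$id != "h2", pts)
  landuse <- lapply(pts, function(p) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(p$x, p$y)),
         properties = list(id = p$id, kind = p$kind, area = p$area))
  })
  for (nm in c("zones", "landuse", "roads")) {
    jsonlite::write_json(list(type = "FeatureCollection",
                              features = get(nm)),
                         file.path(dir, paste0(nm, ".geojson")),
                         auto_unbox = TRUE, digits = NA)
  }
  file.path(dir, paste0(c("zones", "landuse", "roads"), ".geojson"))
}

test_that("a minimal two-zone fixture loads into the expected environment", {
  dir <- withr::local_tempdir()
  f <- write_fixture_city(dir)
  env <- load_environment(f[1], f[2], f[3])
  expect_s3_class(env, "pa_environment")
  expect_equal(nrow(env$zones), 2)
  expect_equal(env$zones$s, c(1, 0.6))
  expect_equal(nrow(env$sites), 5)
  park <- env$sites[env$sites$id == "p1", ]
  expect_equal(park$large, 1L)
  expect_equal(park$zone, 2L)
  expect_equal(sum(env$sites$kind == "home"), 2)
  # both homes reach the school over the 900 m spine
  r <- shortest_route(env, "h1", "sch")
  expect_equal(r$length, 450)
  expect_equal(r$mean_walkability, 0.8)
})

test_that("round trip through GeoJSON preserves the environment", {
  env <- small_env()
  dir <- withr::local_tempdir()
  paths <- env_to_geojson(env, dir)
  env2 <- load_environment(paths[1], paths[2], paths[3])
  expect_equal(env2$zones$simd_quintile, env$zones$simd_quintile)
  expect_equal(env2$zones$s, env$zones$s)
  expect_equal(nrow(env2$sites), nrow(env$sites))
  expect_equal(sort(env2$sites$kind), sort(env$sites$kind))
  expect_equal(env2$sites$area[match(env$sites$id, env2$sites$id)],
               env$sites$area, tolerance = 1e-9)
  expect_equal(nrow(env2$edges), nrow(env$edges))
  # a route between the same two named sites has the same length
  sid <- env$sites$id[env$sites$kind != "home"][1:2]
  expect_equal(shortest_route(env2, sid[1], sid[2])$length,
               shortest_route(env, sid[1], sid[2])$length, tolerance = 1e-6)
})

test_that("schema violations are reported with the feature id", {
  dir <- withr::local_tempdir()
  f <- write_fixture_city(dir, drop_quintile = TRUE)
  expect_error(load_environment(f[1], f[2], f[3]), "simd_quintile")
})

test_that("a zone without homes fails validation", {
  dir <- withr::local_tempdir()
  f <- write_fixture_city(dir, zero_home_zone = TRUE)
  expect_error(load_environment(f[1], f[2], f[3]), "no home")
})
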