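# Track reading, projection, raster and GeoJSON round-trips, landscape
# bundle validation.

write_track_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("read_track parses, sorts and deduplicates Movebank-style CSV", {
  p <- write_track_csv(data.frame(
    timestamp = c("2021-04-20T00:00:00Z", "2021-04-20T01:00:00Z",
                  "2021-04-20T02:00:00Z"),
    longitude = c(9.1, 9.11, 9.12), latitude = c(45.1, 45.11, 45.12)))
  tr <- read_track(p, id = "w1")
  expect_s3_class(tr, "wolf_track")
  expect_equal(nrow(tr$records), 3)
  expect_equal(tr$individual_id, "w1")
  expect_equal(tr$release_lonlat, c(9.1, 45.1))

  # shuffled rows come back sorted
  p2 <- write_track_csv(data.frame(
    timestamp = c("2021-04-20T02:00:00Z", "2021-04-20T00:00:00Z",
                  "2021-04-20T01:00:00Z"),
    longitude = c(9.12, 9.1, 9.11), latitude = c(45.12, 45.1, 45.11)))
  tr2 <- read_track(p2)
  expect_equal(tr2$records$longitude, c(9.1, 9.11, 9.12))

  # duplicated timestamp collapses to first occurrence with a message
  p3 <- write_track_csv(data.frame(
    timestamp = c("2021-04-20T00:00:00Z", "2021-04-20T00:00:00Z",
                  "2021-04-20T01:00:00Z"),
    longitude = c(9.1, 9.2, 9.11), latitude = c(45.1, 45.2, 45.11)))
  expect_message(tr3 <- read_track(p3), "duplicate")
  expect_equal(nrow(tr3$records), 2)
  expect_equal(tr3$records$longitude[1], 9.1)
})

test_that("read_track fails usefully on malformed input", {
  p <- write_track_csv(data.frame(longitude = 9, latitude = 45))
  expect_error(read_track(p), "timestamp")
  p2 <- write_track_csv(data.frame(timestamp = "not-a-time",
                                   longitude = 9, latitude = 45))
  expect_error(read_track(p2), "row 1")
  p3 <- write_track_csv(data.frame(timestamp = "2021-04-20T00:00:00Z",
                                   longitude = 500, latitude = 45))
  expect_error(read_track(p3), "range")
  expect_error(read_track(tempfile()), "not found")
})

test_that("projection is metric, invertible, and rejects geographic CRS", {
  # point on the central meridian at the equator maps to the false origin
  xy0 <- lonlat_to_xy(9, 0, "EPSG:32632")
  expect_equal(unname(xy0[1, 1]), 5e5)
  expect_equal(unname(xy0[1, 2]), 0)

  # 1 km along a meridian: planar distance within 2 m of the geodesic
  skip_if_not_installed("geosphere")
  lat2 <- 45.0089932
  a <- lonlat_to_xy(9.3, 45, "EPSG:32632")
  b <- lonlat_to_xy(9.3, lat2, "EPSG:32632")
  planar <- sqrt(sum((b - a)^2))
  geo <- geosphere::distGeo(c(9.3, 45), c(9.3, lat2))
  expect_lt(abs(planar - geo), 2)

  # round trip to 1e-6 degrees over the zone
  set.seed(42)
  lon <- runif(100, 6.5, 11.5); lat <- runif(100, 36, 60)
  xy <- lonlat_to_xy(lon, lat, "EPSG:32632")
  ll <- xy_to_lonlat(xy[, 1], xy[, 2], "EPSG:32632")
  expect_lt(max(abs(ll[, 1] - lon), abs(ll[, 2] - lat)), 1e-6)

  expect_error(parse_crs("EPSG:4326"), "geographic")
  expect_error(parse_crs("EPSG:99999"), "unrecognised")
  expect_equal(utm_crs_for(9.2, 45.2), "EPSG:32632")
})

test_that("project_track handles empty tracks and carries metadata", {
  tr <- structure(list(individual_id = "w", records = data.frame(
    timestamp = utc(character(0)), longitude = numeric(0),
    latitude = numeric(0)), release_time = NA, release_lonlat = c(NA, NA)),
    class = "wolf_track")
  traj <- project_track(tr, "EPSG:32632")
  expect_equal(nrow(traj), 0)
  expect_error(project_track(tr, "EPSG:4326"), "geographic")
})

test_that("ASCII grid rasters round-trip through disk", {
  set.seed(7)
  r <- wm_raster(matrix(runif(30), 5, 6), 600000, 5000000, 50, "EPSG:32632")
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(r, p)
  r2 <- read_ascii_grid(p)
  expect_lt(max(abs(r2$values - r$values)), 1e-12)
  expect_equal(r2$xmin, r$xmin)
  expect_equal(r2$res, r$res)
  expect_equal(r2$crs, "EPSG:32632")  # sidecar CRS
})

test_that("UD rasters round-trip as density per square metre", {
  v <- matrix(runif(16), 4, 4); v <- v / sum(v)
  ud <- wm_raster(v, 0, 0, 100, "EPSG:32632")
  class(ud) <- c("wm_ud", class(ud))
  p <- tempfile(fileext = ".asc")
  write_ud_raster(ud, p)
  # on-disk values are density (mass / cell area)
  disk <- read_ascii_grid(p)
  expect_equal(sum(disk$values) * 100^2, 1, tolerance = 1e-12)
  ud2 <- read_ud_raster(p)
  expect_lt(max(abs(ud2$values - ud$values)), 1e-12)
})

test_that("GeoJSON lines and points round-trip; empty collections are valid", {
  l1 <- cbind(c(0, 100, 200), c(0, 50, 25.123456789))
  attr(l1, "class_attr") <- "motorway"
  p <- tempfile(fileext = ".geojson")
  write_geojson_lines(list(l1), p, props = list(list(class = "motorway")))
  back <- read_geojson_lines(p)
  expect_equal(length(back), 1)
  expect_lt(max(abs(back[[1]] - l1)), 1e-9)
  expect_equal(attr(back[[1]], "class_attr"), "motorway")

  # empty site list -> valid empty FeatureCollection
  p2 <- tempfile(fileext = ".geojson")
  write_sites(wolfmove:::empty_sites(), p2)
  fc <- jsonlite::fromJSON(p2, simplifyVector = FALSE)
  expect_equal(fc$type, "FeatureCollection")
  expect_equal(length(fc$features), 0)

  # attributes persist exactly
  df <- data.frame(x = 1.5, y = 2.5, diurnality = 0.5, phase = "dispersal")
  p3 <- tempfile(fileext = ".geojson")
  write_geojson_points(df, p3)
  back3 <- read_geojson_points(p3)
  expect_identical(back3$diurnality, 0.5)
  expect_identical(back3$phase, "dispersal")
})

test_that("landscape bundles validate layers, ranges and grids", {
  ls <- tiny_landscape()
  d <- file.path(tempdir(), "bundle1")
  write_landscape(ls, d)
  ls2 <- read_landscape(d)
  expect_equal(ls2$landcover$values, ls$landcover$values)
  expect_equal(length(ls2$roads), 2)
  expect_equal(attr(ls2$roads[[1]], "class_attr"), "motorway")

  # missing layer named in the error
  file.remove(file.path(d, "elevation.asc"))
  expect_error(read_landscape(d), "elevation.asc")

  # density out of [0,1] rejected
  bad <- ls$tree_density
  bad$values[1, 1] <- 1.4
  expect_error(wm_landscape(ls$landcover, bad, ls$settlement_density,
                            ls$elevation), "\\[0, 1\\]")

  # a coarser density grid is resampled with a log message
  coarse <- wm_raster(matrix(0.5, 50, 50), ls$landcover$xmin,
                      ls$landcover$ymin, 40, "EPSG:32632")
  expect_message(
    ls3 <- wm_landscape(ls$landcover, coarse, ls$settlement_density,
                        ls$elevation),
    "resampling")
  expect_equal(dim(ls3$tree_density$values), dim(ls$landcover$values))
})
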