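# Landscape data model and external formats. Rasters travel as ESRI ASCII
# grids (see raster.R); line and point layers as GeoJSON FeatureCollections
# with coordinates in the projected CRS of the bundle.

#' Assemble a landscape from in-memory layers
#'
#' Validates co-registration and value ranges; layers on a different grid
#' than the land cover are resampled onto it (nearest neighbour for the
#' categorical land cover companions, bilinear for continuous rasters) with
#' a log entry.
#'
#' @param landcover Categorical [wm_raster()] of integer codes.
#' @param tree_density,settlement_density Continuous rasters in \[0, 1\].
#' @param elevation Continuous raster, metres a.s.l.
#' @param roads List of polyline coordinate matrices, each with attribute
#'   `class_attr` in `c("motorway", "primary")`.
#' @param rivers List of polyline coordinate matrices.
#' @param classes Named integer codes for at least tree, built, open, water.
#' @return A `wm_landscape` list.
#' @export
wm_landscape <- function(landcover, tree_density, settlement_density,
                         elevation, roads = list(), rivers = list(),
                         classes = c(open = 0L, tree = 1L, built = 2L,
                                     water = 3L)) {
  template <- landcover
  align <- function(r, name, method) {
    if (identical(dim(r$values), dim(template$values)) &&
        isTRUE(all.equal(c(r$xmin, r$ymin, r$res),
                         c(template$xmin, template$ymin, template$res)))) {
      return(r)
    }
    wm_log(sprintf("read_landscape: resampling %s onto land-cover grid (%s)",
                   name, method))
    raster_resample(r, template, method)
  }
  tree_density <- align(tree_density, "tree_density", "bilinear")
  settlement_density <- align(settlement_density, "settlement_density", "bilinear")
  elevation <- align(elevation, "elevation", "bilinear")
  for (nm in c("tree_density", "settlement_density")) {
    v <- get(nm)$values
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      stop(nm, " values outside [0, 1]", call. = FALSE)
    }
  }
  structure(list(landcover = landcover, tree_density = tree_density,
                 settlement_density = settlement_density,
                 elevation = elevation, roads = roads, rivers = rivers,
                 classes = classes, crs = landcover$crs,
                 resolution = landcover$res),
            class = "wm_landscape")
}

#' Read a landscape bundle from a directory
#'
#' Expects `landcover.asc`, `tree_density.asc`, `settlement_density.asc`,
#' `elevation.asc`, `roads.geojson` (LineString features with a `class`
#' property), and `rivers.geojson`. Missing layers raise an error naming the
#' layer; off-grid rasters are resampled onto the land-cover grid.
#'
#' @param dir Bundle directory.
#' @return A `wm_landscape`.
#' @export
read_landscape <- function(dir) {
  need <- c("landcover.asc", "tree_density.asc", "settlement_density.asc",
            "elevation.asc", "roads.geojson", "rivers.geojson")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("landscape bundle is missing layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lc <- read_ascii_grid(file.path(dir, "landcover.asc"))
  wm_landscape(
    landcover = lc,
    tree_density = read_ascii_grid(file.path(dir, "tree_density.asc")),
    settlement_density = read_ascii_grid(file.path(dir, "settlement_density.asc")),
    elevation = read_ascii_grid(file.path(dir, "elevation.asc")),
    roads = read_geojson_lines(file.path(dir, "roads.geojson")),
    rivers = read_geojson_lines(file.path(dir, "rivers.geojson"))
  )
}

#' Write a landscape bundle to a directory
#'
#' @param landscape A `wm_landscape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(landscape$landcover, file.path(dir, "landcover.asc"))
  write_ascii_grid(landscape$tree_density, file.path(dir, "tree_density.asc"))
  write_ascii_grid(landscape$settlement_density,
                   file.path(dir, "settlement_density.asc"))
  write_ascii_grid(landscape$elevation, file.path(dir, "elevation.asc"))
  write_geojson_lines(landscape$roads, file.path(dir, "roads.geojson"),
                      props = lapply(landscape$roads, function(l)
                        list(class = attr(l, "class_attr") %||% "primary")))
  write_geojson_lines(landscape$rivers, file.path(dir, "rivers.geojson"))
  invisible(dir)
}

# ---- GeoJSON helpers ------------------------------------------------------

#' Write polylines as a GeoJSON FeatureCollection
#'
#' @param lines List of 2-column coordinate matrices.
#' @param path Output path.
#' @param props Optional list (same length) of per-feature property lists.
#' @return `path`, invisibly.
#' @export
write_geojson_lines <- function(lines, path, props = NULL) {
  features <- lapply(seq_along(lines), function(i) {
    list(type = "Feature",
         properties = if (is.null(props)) structure(list(), names = character(0)) else props[[i]],
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(lines[[i]])),
                                              function(r) unname(lines[[i]][r, 1:2]))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read LineString features from GeoJSON
#'
#' @param path GeoJSON file.
#' @return List of coordinate matrices; each carries attribute `class_attr`
#'   when the feature has a `class` property.
#' @export
read_geojson_lines <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path, call. = FALSE)
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(fc$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(p[[1]], p[[2]])))
    if (!is.null(f$properties$class)) attr(m, "class_attr") <- f$properties$class
    m
  })
}

#' Write point features as a GeoJSON FeatureCollection
#'
#' @param df Data.frame with `x`, `y` columns; all other columns become
#'   feature properties.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  other <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    pr <- lapply(df[i, other, drop = FALSE], function(v) {
      if (inherits(v, "POSIXt")) format(v, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC") else v
    })
    list(type = "Feature",
         properties = if (length(other)) pr else structure(list(), names = character(0)),
         geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Read Point features from GeoJSON into a data.frame
#'
#' @param path GeoJSON file.
#' @return Data.frame with `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(fc$features)) return(data.frame(x = numeric(0), y = numeric(0)))
  rows <- lapply(fc$features, function(f) {
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      f$properties)
  })
  nm <- unique(unlist(lapply(rows, names)))
  out <- lapply(nm, function(col) {
    vals <- lapply(rows, function(r) r[[col]] %||% NA)
    unlist(vals)
  })
  names(out) <- nm
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---- pipeline outputs -----------------------------------------------------

#' Write a UD raster
#'
#' Cell values are converted from probability mass to density per square
#' metre before writing.
#'
#' @param ud A `wm_ud`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_ud_raster <- function(ud, path) {
  dens <- wm_raster(ud$values / ud$res^2, ud$xmin, ud$ymin, ud$res, ud$crs)
  write_ascii_grid(dens, path, digits = 17)
}

#' Read a UD raster written by [write_ud_raster()]
#'
#' @param path `.asc` path.
#' @return A `wm_ud` with cell values as probability mass.
#' @export
read_ud_raster <- function(path) {
  r <- read_ascii_grid(path)
  ud <- wm_raster(r$values * r$res^2, r$xmin, r$ymin, r$res, r$crs)
  class(ud) <- c("wm_ud", class(ud))
  ud
}

#' Write resting sites as GeoJSON points
#'
#' Persists centroid coordinates plus duration, diurnality, phase and
#' elevation attributes; an empty site list yields a valid empty
#' FeatureCollection.
#'
#' @param sites A `resting_sites` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write_geojson_points(as.data.frame(sites), path)
}

#' Write an isopleth region as GeoJSON
#'
#' The region is written as a MultiPolygon of cell-aligned rectangles with
#' `level` and `area_km2` properties.
#'
#' @param iso A `wm_isopleth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isopleth <- function(iso, path) {
  fc <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(level = iso$level, area_km2 = iso$area_km2,
                      mass = iso$mass),
    geometry = list(type = "MultiPolygon",
                    coordinates = isopleth_polygons(iso))
  )))
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
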