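# Shared fixtures, all built in code.

utc <- function(x) as.POSIXct(x, tz = "UTC")

hourly_times <- function(n, start = "2021-06-01 00:00:00") {
  utc(start) + 3600 * (seq_len(n) - 1)
}

# Build a wolf_traj directly from coordinates (metres) and times.
mk_traj <- function(x, y, times, id = "fix", interval = NULL,
                    ref_lonlat = c(9.2, 45.2)) {
  if (is.null(interval)) {
    interval <- if (length(times) > 1) {
      stats::median(diff(as.numeric(times))) / 3600
    } else NA_real_
  }
  wolfmove:::new_traj(
    data.frame(timestamp = times, x = x, y = y),
    individual_id = id, crs = parse_crs("EPSG:32632"),
    release_time = times[1], release_xy = c(x[1], y[1]),
    ref_lonlat = ref_lonlat, nominal_interval = interval)
}

# Square isopleth region centred at (cx, cy): half-width `half` m, cell
# `res` m, embedded in a frame 3x the square.
mk_square_isopleth <- function(cx, cy, half = 2000, res = 100) {
  n <- ceiling(6 * half / res)
  xmin <- cx - 3 * half
  ymin <- cy - 3 * half
  xs <- xmin + (seq_len(n) - 0.5) * res
  ys <- ymin + n * res - (seq_len(n) - 0.5) * res
  mask <- outer(abs(ys - cy) <= half, abs(xs - cx) <= half, `&`) * 1
  structure(list(level = 0.95,
                 mask = wm_raster(mask, xmin, ymin, res, "EPSG:32632"),
                 area_km2 = sum(mask) * res^2 / 1e6, mass = 0.95),
            class = "wm_isopleth")
}

# Tiny landscape (2 km x 2 km @ 20 m) with one tree block in the west, one
# built block in the north-east, a vertical river at x = 1500 m (local),
# one horizontal motorway and one diagonal primary road. Origin at
# (600000, 5000000) to stay in a valid UTM 32N range.
tiny_landscape <- function() {
  res <- 20
  n <- 100
  x0 <- 600000
  y0 <- 5000000
  lc <- matrix(0L, n, n)
  xs <- x0 + (seq_len(n) - 0.5) * res
  ys <- y0 + n * res - (seq_len(n) - 0.5) * res
  lc[, xs - x0 < 600] <- 1L                          # tree block, west
  lc[ys - y0 > 1500, xs - x0 > 1400] <- 2L           # built block, NE
  river_x <- x0 + 1500
  lc[, abs(xs - river_x) < res / 2] <- 3L            # river ribbon
  smooth <- function(ind) wolfmove:::raster_resample(
    wm_raster(ind, x0, y0, res, "EPSG:32632"),
    wm_raster(ind, x0, y0, res, "EPSG:32632"), "near")$values
  tree_d <- (lc == 1L) * 1
  settl_d <- (lc == 2L) * 1
  elev <- matrix(rep(seq(400, 100, length.out = n), n), n, n)
  mk <- function(v) wm_raster(v, x0, y0, res, "EPSG:32632")
  motorway <- cbind(c(x0, x0 + n * res), c(y0 + 500, y0 + 500))
  attr(motorway, "class_attr") <- "motorway"
  primary <- cbind(c(x0, x0 + n * res), c(y0, y0 + n * res))
  attr(primary, "class_attr") <- "primary"
  suppressMessages(wm_landscape(
    landcover = mk(lc), tree_density = mk(tree_d),
    settlement_density = mk(settl_d), elevation = mk(elev),
    roads = list(motorway, primary),
    rivers = list(cbind(c(river_x, river_x), c(y0, y0 + n * res)))))
}

# Reduced simulation for fast pipeline smoke tests: 12 km landscape, short
# schedule, 6-h fixes.
small_sim_overrides <- function() {
  list(extent_km = 12, n_tree_patches = 15, n_built_clusters = 6,
       n_roads = 4, fix_interval_h = 6,
       phase_schedule = data.frame(
         phase = c("post_release", "settlement", "exploration", "settlement",
                   "dispersal"),
         duration_days = c(4, 25, 3, 10, 12)))
}
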