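# Resting-site detection by spatio-temporal clustering of GPS fixes, site
# diurnality, and the dispersal/plain subset used in the selection analysis.
#
# A 250 m circle is drawn around each fix and the span of consecutive
# subsequent fixes remaining inside it is accumulated; spans covering at
# least 6 consecutive hours are candidate clusters. Overlapping or
# temporally adjacent candidates whose anchor fixes lie within 500 m are
# merged (single linkage) and the site location is the mean coordinate of
# all member fixes.

#' Detect resting sites
#'
#' @param traj A regular-interval `wolf_traj`.
#' @param radius Clustering radius around each anchor fix, metres.
#' @param min_hours Minimum clock-time span (first to last member fix) for a
#'   candidate cluster, hours.
#' @param merge_dist Anchor-to-anchor merge distance, metres.
#' @param phases Optional `wolf_phases`; each site is annotated with the
#'   movement pattern at its start fix.
#' @param elevation Optional elevation [wm_raster()]; each site gains
#'   `elev_m` (at the centroid cell) and `below_300m`.
#' @return A `resting_sites` data.frame: `site_id`, `x`, `y` (centroid),
#'   `start_time`, `end_time`, `duration_h`, `n_fixes`, `first_fix`,
#'   `last_fix` and, when available, `phase`, `elev_m`, `below_300m`.
#' @export
detect_resting_sites <- function(traj, radius = 250, min_hours = 6,
                                 merge_dist = 500, phases = NULL,
                                 elevation = NULL) {
  n <- nrow(traj)
  t <- as.numeric(traj$timestamp)
  nominal_s <- attr(traj, "nominal_interval") * 3600
  if (is.na(nominal_s)) nominal_s <- stats::median(diff(t))
  gap_break <- nominal_s * 1.5  # a longer-than-nominal gap breaks contiguity
  cand <- list()
  for (i in seq_len(n)) {
    j <- i
    while (j < n &&
           (t[j + 1] - t[j]) <= gap_break &&
           sqrt((traj$x[j + 1] - traj$x[i])^2 +
                (traj$y[j + 1] - traj$y[i])^2) <= radius) {
      j <- j + 1L
    }
    if (t[j] - t[i] >= min_hours * 3600) {
      cand[[length(cand) + 1L]] <- c(anchor = i, first = i, last = j)
    }
  }
  if (!length(cand)) return(empty_sites())
  cand <- do.call(rbind, cand)
  # Single-linkage merge of temporally overlapping/adjacent candidates whose
  # anchors are within merge_dist.
  k <- nrow(cand)
  comp <- seq_len(k)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      overlap <- cand[j, "first"] <= cand[i, "last"] + 1L
      if (!overlap) next
      d <- sqrt((traj$x[cand[i, "anchor"]] - traj$x[cand[j, "anchor"]])^2 +
                (traj$y[cand[i, "anchor"]] - traj$y[cand[j, "anchor"]])^2)
      joined <- cand[j, "first"] <= cand[i, "last"]  # share fixes
      if (joined || d <= merge_dist) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  out <- list()
  sid <- 0L
  for (rt in unique(roots)) {
    members <- cand[roots == rt, , drop = FALSE]
    f0 <- min(members[, "first"]); f1 <- max(members[, "last"])
    fx <- f0:f1
    sid <- sid + 1L
    out[[sid]] <- data.frame(
      site_id = sid,
      x = mean(traj$x[fx]), y = mean(traj$y[fx]),
      start_time = traj$timestamp[f0], end_time = traj$timestamp[f1],
      duration_h = (t[f1] - t[f0]) / 3600,
      n_fixes = length(fx), first_fix = f0, last_fix = f1
    )
  }
  sites <- do.call(rbind, out)
  sites <- sites[order(sites$start_time), , drop = FALSE]
  sites$site_id <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  if (!is.null(phases)) sites$phase <- phases$labels[sites$first_fix]
  if (!is.null(elevation)) {
    sites$elev_m <- raster_extract(elevation, sites$x, sites$y)
    sites$below_300m <- sites$elev_m < 300
  }
  structure(sites, class = c("resting_sites", "data.frame"),
            individual_id = attr(traj, "individual_id"),
            ref_lonlat = attr(traj, "ref_lonlat"))
}

empty_sites <- function() {
  structure(data.frame(site_id = integer(0), x = numeric(0), y = numeric(0),
                       start_time = as.POSIXct(character(0), tz = "UTC"),
                       end_time = as.POSIXct(character(0), tz = "UTC"),
                       duration_h = numeric(0), n_fixes = integer(0),
                       first_fix = integer(0), last_fix = integer(0)),
            class = c("resting_sites", "data.frame"))
}

#' Diurnality level of a resting bout
#'
#' Fraction of the occupancy interval falling in daytime out of the time
#' falling in day or night (twilight excluded from both numerator and
#' denominator): 0 is fully nocturnal resting, 1 fully diurnal. The interval
#' is integrated on a fine time grid with the solar calculator.
#'
#' @param start,end `POSIXct` occupancy bounds.
#' @param lat,lon Site location in degrees (for solar geometry).
#' @param step_min Integration step, minutes.
#' @return Diurnality in \[0, 1\], or `NA` (with a warning) when the bout
#'   falls entirely in twilight.
#' @export
diurnality <- function(start, end, lat, lon, step_min = 2) {
  stopifnot(end > start)
  ts <- seq(as.numeric(start), as.numeric(end), by = step_min * 60)
  per <- solar_period(as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
                      lat, lon)
  nd <- sum(per == "day"); nn <- sum(per == "night")
  if (nd + nn == 0) {
    warning("occupancy entirely within twilight; diurnality undefined")
    return(NA_real_)
  }
  nd / (nd + nn)
}

#' Annotate resting sites with diurnality
#'
#' @param sites A `resting_sites` data.frame.
#' @param crs CRS of the site coordinates, for converting centroids back to
#'   longitude/latitude; defaults to the trajectory CRS recorded on `sites`'
#'   parent, else requires `ref_lonlat`.
#' @return `sites` with a `diurnality` column.
#' @export
add_diurnality <- function(sites, crs) {
  if (!nrow(sites)) { sites$diurnality <- numeric(0); return(sites) }
  ll <- xy_to_lonlat(sites$x, sites$y, crs)
  sites$diurnality <- vapply(seq_len(nrow(sites)), function(i) {
    suppressWarnings(diurnality(sites$start_time[i], sites$end_time[i],
                                ll[i, 2], ll[i, 1]))
  }, numeric(1))
  sites
}

#' Subset resting sites to the dispersal trajectory within the plain
#'
#' Keeps sites whose movement pattern is pre-dispersal or dispersal and whose
#' centroid elevation is below 300 m a.s.l. (the lowland plain).
#'
#' @param sites A `resting_sites` data.frame with `phase` and `elev_m`.
#' @param max_elev Elevation cut-off, metres a.s.l.
#' @return The qualifying subset.
#' @export
filter_dispersal_plain <- function(sites, max_elev = 300) {
  stopifnot_cols(sites, c("phase", "elev_m"), what = "resting sites")
  keep <- sites$phase %in% c("pre_dispersal", "dispersal") &
    sites$elev_m < max_elev
  sites[keep, , drop = FALSE]
}
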