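# GPS track I/O and trajectory construction.

#' Read a GPS track from a Movebank-style CSV
#'
#' Expects columns `timestamp` (ISO 8601, UTC), `longitude`, `latitude`
#' (degrees) and optionally `dop`. Rows are sorted by timestamp; duplicate
#' timestamps are collapsed to the first occurrence with a warning.
#'
#' @param path CSV file path.
#' @param id Individual identifier attached to the track.
#' @return A `wolf_track`: list with `individual_id`, `records` (data.frame
#'   with `timestamp`, `longitude`, `latitude`), `release_time`,
#'   `release_lonlat`.
#' @export
read_track <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("timestamp", "longitude", "latitude"),
                 what = paste0("track CSV '", path, "'"))
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in fmts) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(df$timestamp[todo], format = fmt, tz = "UTC")
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp '%s' at data row %d of %s",
                 df$timestamp[bad], bad, path), call. = FALSE)
  }
  if (!is.numeric(df$longitude) || !is.numeric(df$latitude) ||
      any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180)) {
    stop("longitude/latitude out of range in ", path, call. = FALSE)
  }
  o <- order(ts)
  df <- df[o, , drop = FALSE]
  ts <- ts[o]
  dup <- duplicated(ts)
  if (any(dup)) {
    wm_log(sprintf("%s: collapsed %d duplicate timestamp(s) to first occurrence",
                   id, sum(dup)), level = "WARN")
    df <- df[!dup, , drop = FALSE]
    ts <- ts[!dup]
  }
  rec <- data.frame(timestamp = ts, longitude = df$longitude,
                    latitude = df$latitude)
  if ("dop" %in% names(df)) rec$dop <- df$dop
  structure(list(individual_id = id, records = rec,
                 release_time = ts[1],
                 release_lonlat = c(df$longitude[1], df$latitude[1])),
            class = "wolf_track")
}

#' Project a track into a metric CRS
#'
#' @param track A `wolf_track` from [read_track()].
#' @param crs Projected CRS identifier (see [parse_crs()]); a geographic CRS
#'   is rejected.
#' @param nominal_interval Nominal fix interval in hours (attached as
#'   metadata; inferred from the median gap when `NULL`).
#' @return A `wolf_traj`: data.frame of fixes (`timestamp`, `x`, `y`) with
#'   attributes `individual_id`, `crs`, `release_time`, `release_xy`,
#'   `nominal_interval` (hours), `ref_lonlat` (for solar computations).
#' @export
project_track <- function(track, crs, nominal_interval = NULL) {
  p <- parse_crs(crs)
  rec <- track$records
  if (nrow(rec)) {
    xy <- lonlat_to_xy(rec$longitude, rec$latitude, p)
  } else {
    xy <- cbind(x = numeric(0), y = numeric(0))
  }
  fixes <- data.frame(timestamp = rec$timestamp, x = xy[, 1], y = xy[, 2])
  if (is.null(nominal_interval)) {
    nominal_interval <- if (nrow(fixes) > 1) {
      stats::median(diff(as.numeric(fixes$timestamp))) / 3600
    } else NA_real_
  }
  new_traj(fixes, individual_id = track$individual_id, crs = p,
           release_time = track$release_time,
           release_xy = if (nrow(fixes)) c(fixes$x[1], fixes$y[1]) else c(NA, NA),
           ref_lonlat = if (nrow(rec)) colMeans(rec[, c("longitude", "latitude")])
                        else c(NA, NA),
           nominal_interval = nominal_interval)
}

new_traj <- function(fixes, individual_id, crs, release_time, release_xy,
                     ref_lonlat, nominal_interval) {
  structure(fixes,
            individual_id = individual_id, crs = crs,
            release_time = release_time, release_xy = release_xy,
            ref_lonlat = ref_lonlat, nominal_interval = nominal_interval,
            class = c("wolf_traj", "data.frame"))
}

# Copy trajectory metadata onto a (subset) fix data.frame.
traj_like <- function(fixes, traj) {
  new_traj(fixes,
           individual_id = attr(traj, "individual_id"),
           crs = attr(traj, "crs"),
           release_time = attr(traj, "release_time"),
           release_xy = attr(traj, "release_xy"),
           ref_lonlat = attr(traj, "ref_lonlat"),
           nominal_interval = attr(traj, "nominal_interval"))
}

#' @export
print.wolf_traj <- function(x, ...) {
  cat(sprintf("<wolf_traj> %s: %d fixes, nominal interval %s h\n",
              attr(x, "individual_id"), nrow(x),
              format(attr(x, "nominal_interval"))))
  if (nrow(x)) {
    cat(sprintf("  span %s .. %s\n", format(x$timestamp[1], usetz = TRUE),
                format(x$timestamp[nrow(x)], usetz = TRUE)))
  }
  invisible(x)
}
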