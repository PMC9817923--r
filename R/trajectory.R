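# Trajectory regularisation, step geometry, day/night labelling, and
# displacement metrics.

#' Subsample a trajectory to a regular fix schedule
#'
#' Keeps only fixes falling on the requested clock-hour anchors (UTC) within
#' a minute tolerance; when several fixes compete for one anchor slot the one
#' nearest in time wins. This reproduces the regular subsampling used to make
#' trajectories with different collar schedules comparable (e.g. 6-h anchors
#' 00/06/12/18, or 4-h anchors 00/04/08/12/16/20).
#'
#' @param traj A `wolf_traj`.
#' @param interval Nominal interval between anchors, hours.
#' @param anchor_hours Integer clock hours (UTC) that define the schedule;
#'   defaults to `seq(0, 23, by = interval)`.
#' @param tolerance_min Maximum offset (minutes) from an anchor for a fix to
#'   qualify (default 10).
#' @return A regularised `wolf_traj` with `nominal_interval` set to
#'   `interval`.
#' @export
regularize <- function(traj, interval, anchor_hours = NULL,
                       tolerance_min = 10) {
  if (is.null(anchor_hours)) anchor_hours <- seq(0, 23, by = interval)
  anchor_hours <- sort(unique(as.integer(anchor_hours) %% 24L))
  if (length(anchor_hours) > 1 &&
      !all(diff(anchor_hours) == interval)) {
    stop("anchor_hours are not spaced by the stated interval", call. = FALSE)
  }
  t <- as.numeric(traj$timestamp)
  # Nearest anchor slot for each fix: slots are epoch times on the anchor grid.
  day0 <- floor(t / 86400) * 86400
  best_slot <- rep(NA_real_, length(t))
  best_off <- rep(Inf, length(t))
  for (h in anchor_hours) {
    for (d in c(-86400, 0, 86400)) {
      slot <- day0 + d + h * 3600
      off <- abs(t - slot)
      better <- off < best_off
      best_slot[better] <- slot[better]
      best_off[better] <- off[better]
    }
  }
  keep <- best_off <= tolerance_min * 60
  if (!any(keep)) {
    stop("regularize: no fix within tolerance of any anchor; ",
         "check that anchor_hours match the collar schedule", call. = FALSE)
  }
  df <- traj[keep, , drop = FALSE]
  slot <- best_slot[keep]
  off <- best_off[keep]
  # one fix per slot: nearest wins
  o <- order(slot, off)
  df <- df[o, , drop = FALSE][!duplicated(slot[o]), , drop = FALSE]
  rownames(df) <- NULL
  out <- traj_like(df, traj)
  attr(out, "nominal_interval") <- interval
  out
}

#' Compute steps between successive fixes
#'
#' @param traj A `wolf_traj` with at least 2 fixes.
#' @param label_periods Attach a day/night/twilight period to each step from
#'   the solar elevation at the step's temporal midpoint (default `TRUE`).
#' @return A `wolf_steps` data.frame, one row per pair of successive fixes:
#'   `t_from`, `t_to`, `x_from`, `y_from`, `x_to`, `y_to`, `length_m`,
#'   `duration_h`, `heading_rad`, `turning_angle_rad` (`NA` on the first
#'   step), `gap` (`TRUE` when the duration exceeds the nominal interval),
#'   and `period`.
#' @export
compute_steps <- function(traj, label_periods = TRUE) {
  n <- nrow(traj)
  if (n < 2) stop("compute_steps needs at least 2 fixes", call. = FALSE)
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  dur <- diff(as.numeric(traj$timestamp)) / 3600
  heading <- atan2(dy, dx)
  turn <- c(NA, wrap_angle(diff(heading)))
  nominal <- attr(traj, "nominal_interval")
  steps <- data.frame(
    t_from = traj$timestamp[-n], t_to = traj$timestamp[-1],
    x_from = traj$x[-n], y_from = traj$y[-n],
    x_to = traj$x[-1], y_to = traj$y[-1],
    length_m = sqrt(dx^2 + dy^2), duration_h = dur,
    heading_rad = heading, turning_angle_rad = turn,
    gap = if (is.na(nominal)) FALSE else dur > nominal * 1.5
  )
  if (label_periods) {
    ll <- attr(traj, "ref_lonlat")
    mid <- traj$timestamp[-n] + dur * 1800  # midpoint: dur/2 hours in seconds
    steps$period <- solar_period(mid, ll[2], ll[1])
  }
  structure(steps, individual_id = attr(traj, "individual_id"),
            class = c("wolf_steps", "data.frame"))
}

#' Net squared displacement series
#'
#' Squared Euclidean distance of every fix from the first fix (the release
#' site), in km2; the shape of this curve separates settlement, exploration
#' and dispersal movement.
#'
#' @param traj A `wolf_traj`.
#' @return Numeric vector, km2, one value per fix.
#' @export
nsd_series <- function(traj) {
  if (!nrow(traj)) return(numeric(0))
  ((traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2) / 1e6
}

#' Displacement and travel-distance summary
#'
#' Computes the trajectory-level movement metrics: per-day minimum travelled
#' distance, cumulative line distance (sum of all step lengths), cumulative
#' net displacement (release to last fix), maximum net displacement (largest
#' pairwise distance between any two fixes), mean travel speed over steps,
#' and—when a phase labelling with a dispersal segment is supplied—the net
#' dispersal distances from the release site to the last and to the farthest
#' fix of the dispersal phase.
#'
#' @param traj A `wolf_traj`.
#' @param phases Optional `wolf_phases` labelling (see [classify_phases()]).
#' @return A list of class `displacement_summary`; distances in km, speed in
#'   km/h.
#' @export
displacement_summary <- function(traj, phases = NULL) {
  steps <- if (nrow(traj) >= 2) compute_steps(traj, label_periods = FALSE) else NULL
  # each step is assigned to the calendar day (UTC) of its end fix
  daily <- if (!is.null(steps)) {
    tapply(steps$length_m, as.Date(steps$t_to, tz = "UTC"), sum) / 1000
  } else numeric(0)
  cum_line <- if (is.null(steps)) 0 else sum(steps$length_m) / 1000
  n <- nrow(traj)
  cum_net <- if (n) sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2) / 1000 else 0
  max_net <- max_pairwise_km(traj$x, traj$y)
  speeds <- if (is.null(steps)) numeric(0) else steps$length_m / 1000 / steps$duration_h
  disp_last <- disp_far <- NA_real_
  if (!is.null(phases)) {
    di <- which(phases$labels == "dispersal")
    if (length(di)) {
      d <- sqrt((traj$x[di] - traj$x[1])^2 + (traj$y[di] - traj$y[1])^2) / 1000
      disp_last <- d[length(d)]
      disp_far <- max(d)
    }
  }
  structure(list(
    nsd_series = nsd_series(traj),
    min_daily_distance = as.numeric(daily),
    min_daily_distance_mean = if (length(daily)) mean(daily) else NA_real_,
    min_daily_distance_sd = if (length(daily) > 1) stats::sd(daily) else NA_real_,
    cumulative_line_distance = cum_line,
    cumulative_net_displacement = cum_net,
    maximum_net_displacement = max_net,
    mean_speed = if (length(speeds)) mean(speeds) else NA_real_,
    sd_speed = if (length(speeds) > 1) stats::sd(speeds) else NA_real_,
    net_dispersal_last = disp_last,
    net_dispersal_farthest = disp_far
  ), class = "displacement_summary")
}

# Exact maximum pairwise Euclidean distance, km. Brute force in blocks;
# fine at the n of a single collar deployment (~1500 fixes).
max_pairwise_km <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  best <- 0
  block <- 512L
  for (i0 in seq(1, n, by = block)) {
    i <- i0:min(i0 + block - 1L, n)
    dx <- outer(x[i], x, `-`)
    dy <- outer(y[i], y, `-`)
    best <- max(best, max(dx^2 + dy^2))
  }
  sqrt(best) / 1000
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat("Displacement summary (km, km/h):\n")
  cat(sprintf("  minimum daily distance: %.1f +/- %.1f\n",
              x$min_daily_distance_mean, x$min_daily_distance_sd))
  cat(sprintf("  cumulative net displacement: %.1f\n", x$cumulative_net_displacement))
  cat(sprintf("  maximum net displacement: %.1f\n", x$maximum_net_displacement))
  cat(sprintf("  cumulative line distance: %.1f\n", x$cumulative_line_distance))
  cat(sprintf("  mean travel speed: %.2f +/- %.2f\n", x$mean_speed, x$sd_speed))
  if (!is.na(x$net_dispersal_last)) {
    cat(sprintf("  net dispersal (release-last): %.1f\n", x$net_dispersal_last))
    cat(sprintf("  net dispersal (release-farthest): %.1f\n", x$net_dispersal_farthest))
  }
  invisible(x)
}
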