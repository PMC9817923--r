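# Synthetic landscapes and behaviour-switching wolf trajectories with known
# ground truth. The generator emulates the structure observed in collared
# floating wolves in a human-dominated lowland: a patchy mosaic of small
# woods and built clusters in an open matrix crossed by roads and a river;
# an imposed phase schedule (post-release, settlement, exploration,
# pre-dispersal, dispersal); strong day/night step-length asymmetry
# (nocturnal travel several times longer than diurnal); multi-hour, mostly
# diurnal resting bouts whose site choice follows a known multinomial-logit
# preference on the same covariates the inference pipeline extracts.

#' Simulation configuration
#'
#' Defaults describe the reference study conditions: a 20 km lowland
#' landscape at 50 m resolution, hourly collar schedule thinned to 4-h
#' fixes, about seven months of monitoring covering all five movement
#' patterns, nocturnal steps four times the diurnal ones, and roughly one
#' resting bout per day of 6.5-10 h centred on the daylight hours.
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param extent_km Landscape side length, km (large enough that dispersal
#'   is long-range relative to the settlement home range).
#' @param resolution_m Raster cell size, m.
#' @param n_tree_patches,n_built_clusters,n_roads,n_rivers Landscape feature
#'   counts (roads alternate motorway/primary classes).
#' @param phase_schedule Data.frame with `phase` and `duration_days`.
#' @param step_day_mean Named per-phase mean diurnal hourly step (m).
#' @param day_night_ratio Nocturnal/diurnal mean step ratio (> 1).
#' @param step_shape Gamma shape of hourly step lengths.
#' @param turn_rho Named per-phase wrapped-Cauchy concentration of turns.
#' @param rest_bout_rate Expected resting bouts per day.
#' @param rest_duration_h Length-2 range of bout durations (h).
#' @param true_beta Named selection coefficients (on within-choice-set
#'   z-scored covariates) governing rest-site choice; names must be
#'   covariate columns of [extract_covariates()].
#' @param fix_interval_h Emitted fix interval (h); hourly positions are
#'   thinned onto anchors 0, `fix_interval_h`, ... UTC.
#' @param gps_error_m Location error SD added to emitted fixes, m.
#' @param start Release time (UTC).
#' @param crs Projected CRS of the simulated world.
#' @param origin_xy South-west corner of the landscape in CRS coordinates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       extent_km = 40,
                       resolution_m = 50,
                       n_tree_patches = 150,
                       n_built_clusters = 50,
                       n_roads = 6,
                       n_rivers = 1,
                       phase_schedule = data.frame(
                         phase = c("post_release", "settlement", "exploration",
                                   "settlement", "pre_dispersal", "settlement",
                                   "dispersal"),
                         duration_days = c(8, 80, 3, 40, 10, 40, 35)
                       ),
                       step_day_mean = c(post_release = 60, settlement = 100,
                                         exploration = 200, pre_dispersal = 220,
                                         dispersal = 220),
                       day_night_ratio = 4,
                       step_shape = 0.8,
                       turn_rho = c(post_release = 0.1, settlement = 0.2,
                                    exploration = 0.8, pre_dispersal = 0.85,
                                    dispersal = 0.9),
                       rest_bout_rate = 1,
                       rest_duration_h = c(6.5, 10),
                       true_beta = c(tree_density_50 = 1.0,
                                     decay_dist_built = 2.2,
                                     decay_dist_river = -0.35),
                       fix_interval_h = 4,
                       gps_error_m = 15,
                       start = as.POSIXct("2021-04-20 00:00:00", tz = "UTC"),
                       crs = "EPSG:32632",
                       origin_xy = c(530000, 4960000)) {
  stopifnot(day_night_ratio > 1, rest_bout_rate >= 0,
            all(rest_duration_h > 0), extent_km > 0, resolution_m > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic landscape
#'
#' Builds the land-cover mosaic (tree patches and built clusters in an open
#' matrix, one or more river corridors rasterised as water), density rasters
#' by box-smoothing the class indicators, straight/polyline roads with
#' alternating motorway/primary classes, and a north-to-south elevation ramp
#' crossing the 300 m a.s.l. contour (hills in the north, plain in the
#' south). Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `wm_landscape`.
#' @export
make_landscape <- function(cfg) {
  set.seed(cfg$seed)
  size <- cfg$extent_km * 1000
  res <- cfg$resolution_m
  ncell <- round(size / res)
  if (ncell < 40) stop("landscape extent too small for requested features",
                       call. = FALSE)
  x0 <- cfg$origin_xy[1]; y0 <- cfg$origin_xy[2]
  lc <- matrix(0L, ncell, ncell)  # open matrix
  xs <- x0 + (seq_len(ncell) - 0.5) * res
  ys <- y0 + ncell * res - (seq_len(ncell) - 0.5) * res  # north first

  # river(s): smooth north-south polylines with sinusoidal wiggle
  rivers <- lapply(seq_len(cfg$n_rivers), function(i) {
    xr <- x0 + size * stats::runif(1, 0.3, 0.7)
    yy <- seq(y0, y0 + size, length.out = 200)
    amp <- size * 0.06
    ph <- stats::runif(1, 0, 2 * pi)
    cbind(xr + amp * sin(yy / size * 4 * pi + ph), yy)
  })

  disc <- function(cx, cy, rad, code) {
    ci <- which(abs(xs - cx) <= rad)
    ri <- which(abs(ys - cy) <= rad)
    if (!length(ci) || !length(ri)) return(invisible(NULL))
    sel <- outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`) <= rad^2
    sub <- lc[ri, ci, drop = FALSE]
    sub[sel] <- code
    lc[ri, ci] <<- sub
    invisible(NULL)
  }
  # tree patches: about 40% hug the river corridor(s), the rest anywhere
  for (i in seq_len(cfg$n_tree_patches)) {
    rad <- stats::runif(1, 200, 700)
    if (cfg$n_rivers > 0 && stats::runif(1) < 0.4) {
      rv <- rivers[[sample.int(cfg$n_rivers, 1)]]
      p <- rv[sample.int(nrow(rv), 1), ]
      cx <- p[1] + stats::rnorm(1, 0, 300)
      cy <- p[2] + stats::rnorm(1, 0, 300)
    } else {
      cx <- x0 + size * stats::runif(1, 0.03, 0.97)
      cy <- y0 + size * stats::runif(1, 0.03, 0.97)
    }
    disc(cx, cy, rad, 1L)
  }
  for (i in seq_len(cfg$n_built_clusters)) {
    disc(x0 + size * stats::runif(1, 0.05, 0.95),
         y0 + size * stats::runif(1, 0.05, 0.95),
         stats::runif(1, 300, 1200), 2L)
  }
  # rasterise rivers as water (overrides other classes)
  for (rv in rivers) {
    for (s in seq_len(nrow(rv) - 1)) {
      L <- sqrt(sum((rv[s + 1, ] - rv[s, ])^2))
      tt <- seq(0, 1, length.out = max(2, ceiling(L / (res / 2))))
      px <- rv[s, 1] + tt * (rv[s + 1, 1] - rv[s, 1])
      py <- rv[s, 2] + tt * (rv[s + 1, 2] - rv[s, 2])
      rc <- cbind(pmin(pmax(ncell - floor((py - y0) / res), 1), ncell),
                  pmin(pmax(floor((px - x0) / res) + 1, 1), ncell))
      lc[rc] <- 3L
    }
  }

  # roads: straightish polylines spanning the extent, classes alternating
  roads <- lapply(seq_len(cfg$n_roads), function(i) {
    horiz <- i %% 2 == 0
    frac <- stats::runif(1, 0.15, 0.85)
    jig <- stats::rnorm(3, 0, size * 0.03)
    if (horiz) {
      m <- cbind(seq(x0, x0 + size, length.out = 5),
                 y0 + size * frac + c(0, jig, 0))
    } else {
      m <- cbind(x0 + size * frac + c(0, jig, 0),
                 seq(y0, y0 + size, length.out = 5))
    }
    attr(m, "class_attr") <- if (i <= ceiling(cfg$n_roads / 2)) "motorway" else "primary"
    m
  })

  smooth9 <- function(ind, passes = 3) {
    v <- ind
    for (p in seq_len(passes)) {
      padded <- rbind(v[1, ], v, v[nrow(v), ])
      padded <- cbind(padded[, 1], padded, padded[, ncol(padded)])
      n <- nrow(v); m <- ncol(v)
      v <- (padded[1:n, 1:m] + padded[1:n, 2:(m + 1)] + padded[1:n, 3:(m + 2)] +
            padded[2:(n + 1), 1:m] + padded[2:(n + 1), 2:(m + 1)] + padded[2:(n + 1), 3:(m + 2)] +
            padded[3:(n + 2), 1:m] + padded[3:(n + 2), 2:(m + 1)] + padded[3:(n + 2), 3:(m + 2)]) / 9
    }
    v
  }
  tree_d <- smooth9((lc == 1L) * 1)
  settl_d <- smooth9((lc == 2L) * 1)

  # elevation: ramp from 500 m at the north edge to 50 m at the south edge
  elev <- matrix(rep(seq(500, 50, length.out = ncell), ncell), ncell, ncell)

  mk <- function(v) wm_raster(v, x0, y0, res, cfg$crs)
  wm_landscape(landcover = mk(lc), tree_density = mk(tree_d),
               settlement_density = mk(settl_d), elevation = mk(elev),
               roads = roads, rivers = rivers)
}

# wrapped-Cauchy turning angles via inverse CDF
rwrappedcauchy <- function(n, rho) {
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  u <- stats::runif(n)
  wrap_angle(2 * atan((1 - rho) / (1 + rho) * tan(pi * (u - 0.5))))
}

#' Simulate a GPS-collared wolf over a synthetic landscape
#'
#' Hourly positions follow a correlated random walk with per-phase,
#' per-period gamma step lengths and wrapped-Cauchy turns. Settlement phases
#' are tethered to an anchor (headings steer home beyond a soft radius);
#' exploration and pre-dispersal are biased out-and-back excursions beyond
#' the settlement range; dispersal is persistently directional towards
#' successive distant targets in the southern plain and never returns.
#' Resting bouts are inserted at the configured daily rate, mostly in
#' daylight; each bout's site is chosen among 50 candidates within 2 km by a
#' multinomial logit with `cfg$true_beta` on covariates extracted with the
#' same code path the inference uses. Hourly positions are thinned onto the
#' configured fix schedule and observed with GPS error.
#'
#' @param cfg A [sim_config()].
#' @param landscape A `wm_landscape` from [make_landscape()] (regenerated
#'   from `cfg` when omitted).
#' @return A list of class `sim_wolf`: `traj` (a `wolf_traj`), `truth` (list
#'   with per-fix `phase`, planted `rest_sites` data.frame, `true_beta`),
#'   `landscape`.
#' @export
simulate_wolf <- function(cfg, landscape = NULL) {
  if (is.null(landscape)) landscape <- make_landscape(cfg)
  set.seed(cfg$seed + 1000003L)
  size <- cfg$extent_km * 1000
  x0 <- cfg$origin_xy[1]; y0 <- cfg$origin_xy[2]
  inset <- 500
  sched <- cfg$phase_schedule
  hours_per <- round(sched$duration_days * 24)
  n_h <- sum(hours_per)
  phase_h <- rep(sched$phase, hours_per)
  seg_id_h <- rep(seq_len(nrow(sched)), hours_per)
  times <- cfg$start + (seq_len(n_h) - 1) * 3600

  ctr <- xy_to_lonlat(x0 + size / 2, y0 + size / 2, cfg$crs)
  period_h <- solar_period(times, ctr[2], ctr[1])

  # release in the northern hills (above the 300 m contour)
  release <- c(x0 + size * stats::runif(1, 0.35, 0.65),
               y0 + size * stats::runif(1, 0.78, 0.88))
  # covariates used by the choice model
  beta <- cfg$true_beta
  radii_d <- as.numeric(stats::na.omit(sub("^(tree|settlement)_density_", "",
                                           grep("density_", names(beta), value = TRUE))))
  radii_m <- as.numeric(stats::na.omit(sub("^patch_density_", "",
                                           grep("^patch_density_", names(beta), value = TRUE))))
  if (!length(radii_d)) radii_d <- 50
  if (!length(radii_m)) radii_m <- 250

  pos <- matrix(NA_real_, n_h, 2)
  pos[1, ] <- release
  heading <- stats::runif(1, -pi, pi)
  anchor <- release
  excursion_bearing <- NA_real_
  target <- NA
  resting_until <- 0
  rest_site <- NULL
  rest_log <- list()
  next_bout_day <- NA_integer_
  settle_radius <- 1500

  pick_rest_site <- function(p, start_time, dur_h) {
    ncand <- 50L
    ang <- stats::runif(ncand, 0, 2 * pi)
    rad <- 2000 * sqrt(stats::runif(ncand))
    cx <- pmin(pmax(p[1] + rad * cos(ang), x0 + inset), x0 + size - inset)
    cy <- pmin(pmax(p[2] + rad * sin(ang), y0 + inset), y0 + size - inset)
    cov <- extract_covariates(cbind(cx, cy), landscape,
                              radii_density = radii_d, radii_metrics = radii_m,
                              decay_scale = 500, columns = names(beta))
    z <- as.matrix(cov[, names(beta), drop = FALSE])
    sds <- apply(z, 2, stats::sd)
    sds[sds == 0] <- 1
    z <- sweep(sweep(z, 2, colMeans(z)), 2, sds, "/")
    u <- drop(z %*% beta)
    pr <- exp(u - max(u)); pr <- pr / sum(pr)
    j <- sample.int(ncand, 1, prob = pr)
    c(cx[j], cy[j])
  }

  day_of <- floor(as.numeric(times - cfg$start) / 86400)
  bout_today <- stats::runif(length(unique(day_of))) < cfg$rest_bout_rate
  # bout start hour (UTC) near mid-morning local so bouts sit in daylight
  bout_start_h <- pmax(3, pmin(9, round(stats::rnorm(length(bout_today), 6, 1))))

  cur_seg <- 1L
  for (i in 2:n_h) {
    ph <- phase_h[i]
    seg <- seg_id_h[i]
    if (seg != cur_seg) {
      cur_seg <- seg
      # a settlement phase entered after dispersal settles where the wolf is
      # now (immediate dispersers settle away from the release site)
      if (ph == "settlement" &&
          "dispersal" %in% phase_h[seq_len(i - 1)]) {
        anchor <- pos[i - 1, ]
      }
      excursion_bearing <- NA_real_
    }
    t_in_seg <- sum(seg_id_h[1:i] == seg)
    seg_len <- hours_per[seg]

    if (i <= resting_until) {
      pos[i, ] <- rest_site + stats::rnorm(2, 0, 10)
      next
    }
    # start a resting bout?
    d <- day_of[i] + 1L
    hr <- as.integer(format(times[i], "%H", tz = "UTC"))
    if (bout_today[d] && hr == bout_start_h[d] && i > 1) {
      dur <- stats::runif(1, cfg$rest_duration_h[1], cfg$rest_duration_h[2])
      site <- pick_rest_site(pos[i - 1, ], times[i], dur)
      resting_until <- min(n_h, i + ceiling(dur) - 1)
      rest_site <- site
      rest_log[[length(rest_log) + 1L]] <- data.frame(
        x = site[1], y = site[2],
        start_time = times[i], end_time = times[min(n_h, resting_until)],
        duration_h = ceiling(dur) - 1, phase = ph
      )
      pos[i, ] <- site + stats::rnorm(2, 0, 10)
      next
    }

    per <- period_h[i]
    mday <- cfg$step_day_mean[[ph]]
    mean_step <- switch(per,
      day = mday,
      night = mday * cfg$day_night_ratio,
      twilight = mday * sqrt(cfg$day_night_ratio))
    L <- stats::rgamma(1, shape = cfg$step_shape,
                       scale = mean_step / cfg$step_shape)
    rho <- cfg$turn_rho[[ph]]

    if (ph %in% c("exploration", "pre_dispersal")) {
      if (t_in_seg <= 2 || is.na(excursion_bearing)) {
        excursion_bearing <- stats::runif(1, -pi, pi)
      }
      # outbound for the first half, then steer home
      bear <- if (t_in_seg < seg_len / 2) excursion_bearing else
        atan2(anchor[2] - pos[i - 1, 2], anchor[1] - pos[i - 1, 1])
      heading <- bear + rwrappedcauchy(1, rho)
      # excursions travel at night-like speeds to get beyond the home range
      L <- max(L, stats::rgamma(1, shape = cfg$step_shape,
                                scale = mean_step / cfg$step_shape))
    } else if (ph == "dispersal") {
      if (length(target) < 2 || sqrt(sum((pos[i - 1, ] - target)^2)) < 1000) {
        # next waypoint: far, in the southern plain
        target <- c(x0 + size * stats::runif(1, 0.1, 0.9),
                    y0 + size * stats::runif(1, 0.05, 0.35))
      }
      bear <- atan2(target[2] - pos[i - 1, 2], target[1] - pos[i - 1, 1])
      heading <- bear + rwrappedcauchy(1, rho)
    } else if (ph == "settlement") {
      dist_home <- sqrt(sum((pos[i - 1, ] - anchor)^2))
      if (dist_home > settle_radius) {
        heading <- atan2(anchor[2] - pos[i - 1, 2], anchor[1] - pos[i - 1, 1]) +
          rwrappedcauchy(1, 0.5)
      } else {
        heading <- heading + rwrappedcauchy(1, rho)
      }
    } else {  # post_release: cramped non-directional wander near release
      heading <- heading + rwrappedcauchy(1, rho)
      if (sqrt(sum((pos[i - 1, ] - release)^2)) > 500) {
        heading <- atan2(release[2] - pos[i - 1, 2], release[1] - pos[i - 1, 1])
      }
    }
    p <- pos[i - 1, ] + L * c(cos(heading), sin(heading))
    # reflect at the landscape boundary
    for (dmn in 1:2) {
      lo <- cfg$origin_xy[dmn] + inset
      hi <- cfg$origin_xy[dmn] + size - inset
      if (p[dmn] < lo) p[dmn] <- lo + (lo - p[dmn])
      if (p[dmn] > hi) p[dmn] <- hi - (p[dmn] - hi)
      p[dmn] <- min(max(p[dmn], lo), hi)
    }
    pos[i, ] <- p
  }

  # thin onto the fix schedule and add GPS error
  hr_utc <- as.integer(format(times, "%H", tz = "UTC"))
  keep <- hr_utc %% cfg$fix_interval_h == 0
  obs <- pos[keep, , drop = FALSE] +
    matrix(stats::rnorm(2 * sum(keep), 0, cfg$gps_error_m), ncol = 2)
  fixes <- data.frame(timestamp = times[keep], x = obs[, 1], y = obs[, 2])
  ctr_ll <- xy_to_lonlat(mean(fixes$x), mean(fixes$y), cfg$crs)
  traj <- new_traj(fixes, individual_id = sprintf("SIM%04d", cfg$seed),
                   crs = parse_crs(cfg$crs),
                   release_time = times[1], release_xy = release,
                   ref_lonlat = c(ctr_ll[1], ctr_ll[2]),
                   nominal_interval = cfg$fix_interval_h)
  truth <- list(
    phase = phase_h[keep],
    rest_sites = if (length(rest_log)) do.call(rbind, rest_log) else NULL,
    true_beta = beta,
    release = release
  )
  structure(list(traj = traj, truth = truth, landscape = landscape),
            class = "sim_wolf")
}

#' Simulate matched case-control strata with known coefficients
#'
#' Generates independent strata of 1 used + `n_avail` available locations
#' with standard-normal covariates; the used row is drawn by conditional
#' logit with the supplied coefficients. A direct generator for validating
#' [fit_clr()] and [dredge_average()] without the full landscape machinery.
#'
#' @param n_strata Number of strata.
#' @param beta Named numeric coefficient vector.
#' @param n_avail Available locations per stratum.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return List of per-stratum covariate matrices, used row first.
#' @export
simulate_clr_strata <- function(n_strata, beta, n_avail = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(beta)
  nm <- names(beta) %||% paste0("x", seq_len(k))
  lapply(seq_len(n_strata), function(s) {
    X <- matrix(stats::rnorm((n_avail + 1) * k), ncol = k,
                dimnames = list(NULL, nm))
    u <- drop(X %*% beta)
    p <- exp(u - max(u)); p <- p / sum(p)
    used <- sample.int(n_avail + 1, 1, prob = p)
    X[c(used, setdiff(seq_len(n_avail + 1), used)), , drop = FALSE]
  })
}
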