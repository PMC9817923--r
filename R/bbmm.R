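# Brownian bridge movement model (BBMM) utilisation distribution.
#
# Between each pair of successive fixes the animal's position is modelled as
# a Brownian bridge with diffusion coefficient sigma2_m (m^2/s), observed
# with isotropic Gaussian location error of SD delta at both endpoints. The
# UD is the time-weighted average over bridges of the positional density,
# integrated over the bridge with the midpoint rule. The estimator
# accommodates irregular time lags and location error, so UDs from collars
# with different fix schedules are comparable.

#' BBMM parameters
#'
#' @param sigma2_m Brownian motion variance, m^2/s (>= 0).
#' @param delta Location error SD in metres; default 30 m (about twice the
#'   nominal accuracy of the GPS collars).
#' @param grid_resolution UD grid cell size, metres.
#' @param integration_points Midpoint-rule nodes per bridge.
#' @param max_gap_days Bridges spanning more than this many days are excluded
#'   from the UD (collar outages would otherwise smear probability mass).
#' @param max_cells Cap on the UD grid size.
#' @return A list of class `bbmm_params`.
#' @export
bbmm_params <- function(sigma2_m, delta = 30, grid_resolution = 100,
                        integration_points = 30, max_gap_days = 7,
                        max_cells = 4e6) {
  stopifnot(sigma2_m >= 0, delta > 0, grid_resolution > 0,
            integration_points >= 1)
  structure(list(sigma2_m = sigma2_m, delta = delta,
                 grid_resolution = grid_resolution,
                 integration_points = as.integer(integration_points),
                 max_gap_days = max_gap_days, max_cells = max_cells),
            class = "bbmm_params")
}

#' Estimate the Brownian motion variance by leave-one-out likelihood
#'
#' Every second interior fix is withheld; under the bridge model its observed
#' position given its observed neighbours is bivariate normal with mean the
#' time-linear interpolation and per-coordinate variance
#' `T a (1-a) sigma2_m + (1 + (1-a)^2 + a^2) delta^2`
#' (`a` the time fraction, `T` the bridge span in seconds): the bridge
#' variance plus the location-error contributions of the two interpolated
#' endpoints and of the withheld fix itself. The likelihood of the withheld
#' fixes is maximised over `sigma2_m` on a log-spaced bracket.
#'
#' @param traj A `wolf_traj` with at least 3 fixes.
#' @param delta Location error SD, metres.
#' @param lower,upper Bracket for `sigma2_m`, m^2/s.
#' @param tol Relative optimisation tolerance.
#' @return Estimated `sigma2_m` (m^2/s).
#' @export
estimate_sigma2m <- function(traj, delta = 30, lower = 1e-8, upper = 1e4,
                             tol = 1e-6) {
  n <- nrow(traj)
  if (n < 3) stop("estimate_sigma2m needs at least 3 fixes", call. = FALSE)
  t <- as.numeric(traj$timestamp)
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing",
                              call. = FALSE)
  idx <- seq(2L, n - 1L, by = 2L)  # leave-one-out set: alternate interior fixes
  T_i <- t[idx + 1L] - t[idx - 1L]
  ok <- T_i > 0
  if (!all(ok)) {
    wm_log("estimate_sigma2m: skipping degenerate zero-time bridge(s)",
           level = "WARN")
    idx <- idx[ok]; T_i <- T_i[ok]
  }
  a <- (t[idx] - t[idx - 1L]) / T_i
  mx <- (1 - a) * traj$x[idx - 1L] + a * traj$x[idx + 1L]
  my <- (1 - a) * traj$y[idx - 1L] + a * traj$y[idx + 1L]
  rx <- traj$x[idx] - mx
  ry <- traj$y[idx] - my
  negll <- function(log_s2) {
    v <- T_i * a * (1 - a) * exp(log_s2) + (1 + (1 - a)^2 + a^2) * delta^2
    sum(log(v) + (rx^2 + ry^2) / (2 * v))
  }
  opt <- stats::optimize(negll, interval = log(c(lower, upper)),
                         tol = tol)
  # prefer the smaller boundary when the optimum sits flush against it
  if (negll(log(lower)) <= opt$objective + 1e-12) return(lower)
  exp(opt$minimum)
}

#' Compute the BBMM utilisation distribution
#'
#' @param traj A `wolf_traj` with at least 2 fixes.
#' @param params A [bbmm_params()] object.
#' @return A `wm_ud`: a [wm_raster()] whose cell values are per-cell
#'   probability *mass* summing to 1, with attributes `params` and
#'   `total_time_s`.
#' @export
compute_ud <- function(traj, params) {
  stopifnot(inherits(params, "bbmm_params"))
  n <- nrow(traj)
  if (n < 2) stop("compute_ud needs at least 2 fixes", call. = FALSE)
  t <- as.numeric(traj$timestamp)
  T_i <- diff(t)
  keep <- T_i > 0 & T_i <= params$max_gap_days * 86400
  if (any(!keep)) {
    wm_log(sprintf("compute_ud: excluding %d bridge(s) longer than %g days",
                   sum(!keep), params$max_gap_days))
  }
  if (!any(keep)) stop("no usable bridges after gap filtering", call. = FALSE)
  m <- params$integration_points
  al <- (seq_len(m) - 0.5) / m
  sig_max <- sqrt(max(T_i[keep]) * 0.25 * params$sigma2_m + params$delta^2)
  pad <- 3 * sig_max
  res <- params$grid_resolution
  xmin <- floor((min(traj$x) - pad) / res) * res
  ymin <- floor((min(traj$y) - pad) / res) * res
  ncol_ <- ceiling((max(traj$x) + pad - xmin) / res)
  nrow_ <- ceiling((max(traj$y) + pad - ymin) / res)
  if (as.double(nrow_) * ncol_ > params$max_cells) {
    stop(sprintf(paste0("UD grid would need %d cells (cap %g); ",
                        "use a coarser grid_resolution"),
                 nrow_ * ncol_, params$max_cells), call. = FALSE)
  }
  xs <- xmin + (seq_len(ncol_) - 0.5) * res
  ys_desc <- ymin + nrow_ * res - (seq_len(nrow_) - 0.5) * res
  dens <- matrix(0, nrow_, ncol_)
  T_tot <- sum(T_i[keep])
  for (i in which(keep)) {
    w_node <- T_i[i] / (m * T_tot)
    for (k in seq_len(m)) {
      a <- al[k]
      mux <- (1 - a) * traj$x[i] + a * traj$x[i + 1L]
      muy <- (1 - a) * traj$y[i] + a * traj$y[i + 1L]
      s2 <- T_i[i] * a * (1 - a) * params$sigma2_m +
        ((1 - a)^2 + a^2) * params$delta^2
      s <- sqrt(s2)
      ci <- which(abs(xs - mux) <= 6 * s)
      ri <- which(abs(ys_desc - muy) <= 6 * s)
      if (!length(ci) || !length(ri)) next
      # exact per-cell Gaussian mass from the CDF differences
      gx <- diff(stats::pnorm(c(xs[ci] - res / 2, xs[ci][length(ci)] + res / 2),
                              mux, s))
      gy <- -diff(stats::pnorm(c(ys_desc[ri] + res / 2,
                                 ys_desc[ri][length(ri)] - res / 2),
                               muy, s))
      dens[ri, ci] <- dens[ri, ci] + w_node * tcrossprod(gy, gx)
    }
  }
  dens <- dens / sum(dens)
  ud <- wm_raster(dens, xmin, ymin, res, attr(traj, "crs"))
  class(ud) <- c("wm_ud", class(ud))
  attr(ud, "params") <- params
  attr(ud, "total_time_s") <- T_tot
  ud
}

#' Extract a probability isopleth from a UD
#'
#' Cells are ranked by density and accumulated greedily until the requested
#' probability mass is enclosed; the enclosed-cell set defines the isopleth
#' region and its area.
#'
#' @param ud A `wm_ud` from [compute_ud()].
#' @param level Probability level in (0, 1); 0.95 gives the settlement area.
#' @return A `wm_isopleth`: list with `level`, `mask` (logical [wm_raster()]),
#'   `area_km2`, `mass` (actual enclosed mass).
#' @export
isopleth <- function(ud, level = 0.95) {
  stopifnot(level > 0, level < 1)
  v <- as.numeric(ud$values)
  o <- order(v, decreasing = TRUE)
  cs <- cumsum(v[o])
  ncell <- which(cs >= level)[1]
  mask <- matrix(FALSE, nrow(ud$values), ncol(ud$values))
  mask[o[seq_len(ncell)]] <- TRUE
  structure(list(
    level = level,
    mask = wm_raster(mask * 1, ud$xmin, ud$ymin, ud$res, ud$crs),
    area_km2 = ncell * ud$res^2 / 1e6,
    mass = cs[ncell]
  ), class = "wm_isopleth")
}

#' Main settlement area: the largest connected component of an isopleth
#'
#' A 95% isopleth computed over a full deployment encloses, besides the
#' settlement area, low-density ribbons along travel corridors and resting
#' stopovers. The settlement area proper is the isopleth's dominant
#' connected component (8-connectivity, largest enclosed mass).
#'
#' @param iso A `wm_isopleth`.
#' @param ud The `wm_ud` the isopleth was cut from (for component masses).
#' @return A `wm_isopleth` restricted to the main component; `mass` is the
#'   mass actually enclosed by that component.
#' @export
main_component <- function(iso, ud) {
  lab <- label_components_8(iso$mask$values > 0)
  k <- max(lab)
  if (k <= 1) return(iso)
  mass_by <- vapply(seq_len(k), function(l) sum(ud$values[lab == l]),
                    numeric(1))
  keep <- which.max(mass_by)
  mask <- (lab == keep) * 1
  structure(list(level = iso$level,
                 mask = wm_raster(mask, iso$mask$xmin, iso$mask$ymin,
                                  iso$mask$res, iso$mask$crs),
                 area_km2 = sum(mask) * iso$mask$res^2 / 1e6,
                 mass = mass_by[keep]),
            class = "wm_isopleth")
}

#' Test points against an isopleth region
#'
#' @param iso A `wm_isopleth`.
#' @param x,y Coordinates (m).
#' @param buffer Tolerance (m): points within `buffer` of a contained cell
#'   centre count as inside (0 = cell membership only).
#' @return Logical vector.
#' @export
isopleth_contains <- function(iso, x, y, buffer = 0) {
  inside <- raster_extract(iso$mask, x, y)
  inside[is.na(inside)] <- 0
  inside <- inside > 0
  if (buffer > 0 && !all(inside)) {
    cc <- class_cell_coords(iso$mask, 1)
    if (nrow(cc)) {
      out_idx <- which(!inside)
      for (i in out_idx) {
        if (min((cc[, 1] - x[i])^2 + (cc[, 2] - y[i])^2) <= buffer^2) {
          inside[i] <- TRUE
        }
      }
    }
  }
  inside
}

# Row-run rectangles of an isopleth mask as a GeoJSON-ready MultiPolygon
# coordinate list (each rectangle a closed ring, lon/lat order = x/y in CRS).
isopleth_polygons <- function(iso) {
  m <- iso$mask
  nr <- nrow(m$values)
  res <- m$res
  ymax <- m$ymin + nr * res
  polys <- list()
  for (i in seq_len(nr)) {
    row <- m$values[i, ] > 0
    if (!any(row)) next
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ytop <- ymax - (i - 1) * res
    ybot <- ytop - res
    for (j in which(r$values)) {
      x0 <- m$xmin + (starts[j] - 1) * res
      x1 <- m$xmin + ends[j] * res
      ring <- list(c(x0, ybot), c(x1, ybot), c(x1, ytop), c(x0, ytop),
                   c(x0, ybot))
      polys[[length(polys) + 1L]] <- list(ring)
    }
  }
  polys
}

#' @export
print.wm_isopleth <- function(x, ...) {
  cat(sprintf("<wm_isopleth> level %.2f: area %.2f km2 (mass %.4f)\n",
              x$level, x$area_km2, x$mass))
  invisible(x)
}
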