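# Brownian bridge UD: estimator contracts, closed-form and Monte Carlo
# oracles, isopleth geometry.

two_fix_traj <- function(sep = 200, dt_h = 1) {
  mk_traj(c(0, sep), c(0, 0), utc("2021-06-01 00:00:00") + c(0, dt_h * 3600))
}

test_that("sigma2 estimation contracts: minimum fixes, degenerate geometry", {
  expect_error(estimate_sigma2m(two_fix_traj()), "at least 3")
  # fixes exactly on the interpolation line: process variance collapses to 0
  n <- 21
  traj <- mk_traj(seq(0, 2000, length.out = n), seq(0, 1000, length.out = n),
                  hourly_times(n))
  est <- estimate_sigma2m(traj, delta = 1e-3)
  expect_lt(est, 1e-6)
})

test_that("sigma2 is recovered from Brownian tracks observed with error", {
  est <- vapply(1:5, function(r) {
    set.seed(100 + r)
    n <- 201; dt <- 3600; s2 <- 0.5; delta <- 30
    x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2 * dt))))
    y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(s2 * dt))))
    traj <- mk_traj(x + rnorm(n, 0, delta), y + rnorm(n, 0, delta),
                    hourly_times(n))
    estimate_sigma2m(traj, delta = delta)
  }, numeric(1))
  expect_lt(abs(median(est) - 0.5), 0.2)
})

test_that("UD mass is 1 and is invariant to time reversal", {
  set.seed(5)
  n <- 30
  traj <- mk_traj(cumsum(rnorm(n, 0, 300)), cumsum(rnorm(n, 0, 300)),
                  hourly_times(n))
  p <- bbmm_params(sigma2_m = 0.5, grid_resolution = 50)
  ud <- compute_ud(traj, p)
  expect_equal(sum(ud$values), 1, tolerance = 1e-6)
  expect_true(all(ud$values >= 0))

  rev_traj <- mk_traj(rev(traj$x), rev(traj$y), traj$timestamp)
  ud_rev <- compute_ud(rev_traj, p)
  expect_lt(max(abs(ud$values - ud_rev$values)), 1e-9)
})

test_that("zero-process-variance bridge matches the closed-form mixture", {
  # sigma2_m = 0: the bridge density is a mixture over alpha of circular
  # Gaussians centred on the interpolation with SD from the endpoint error
  # terms only. Oracle: direct quadrature of the closed form on the grid.
  delta <- 30
  sep <- 200
  traj <- two_fix_traj(sep = sep)
  p <- bbmm_params(sigma2_m = 0, delta = delta, grid_resolution = 10,
                   integration_points = 50)
  ud <- compute_ud(traj, p)
  xs <- wolfmove:::raster_xcoords(ud)
  ys <- wolfmove:::raster_ycoords(ud)
  alphas <- seq(1 / 2000, 1 - 1 / 2000, length.out = 1000)
  oracle <- matrix(0, nrow(ud$values), ncol(ud$values))
  for (a in alphas) {
    s <- delta * sqrt((1 - a)^2 + a^2)
    gx <- dnorm(xs, a * sep, s)
    gy <- dnorm(ys, 0, s)
    oracle <- oracle + tcrossprod(gy, gx)
  }
  oracle <- oracle / sum(oracle)
  tv <- 0.5 * sum(abs(oracle - ud$values))
  expect_lt(tv, 0.01)
})

test_that("gridded UD matches a Monte Carlo draw of bridge positions", {
  # two-bridge track vs 1e5 simulated positions: total variation < 0.02
  set.seed(77)
  traj <- mk_traj(c(0, 220, 380), c(0, 120, -60),
                  utc("2021-06-01 00:00:00") + c(0, 3600, 7200))
  s2 <- 0.01; delta <- 30
  p <- bbmm_params(sigma2_m = s2, delta = delta, grid_resolution = 50,
                   integration_points = 60)
  ud <- compute_ud(traj, p)
  nmc <- 1e5
  T_i <- c(3600, 3600)
  br <- sample.int(2, nmc, replace = TRUE, prob = T_i / sum(T_i))
  al <- runif(nmc)
  mx <- (1 - al) * traj$x[br] + al * traj$x[br + 1]
  my <- (1 - al) * traj$y[br] + al * traj$y[br + 1]
  sd_b <- sqrt(T_i[br] * al * (1 - al) * s2 + ((1 - al)^2 + al^2) * delta^2)
  px <- rnorm(nmc, mx, sd_b)
  py <- rnorm(nmc, my, sd_b)
  rc <- wolfmove:::raster_rowcol(ud, px, py)
  ok <- !is.na(rc[, 1])
  counts <- matrix(0, nrow(ud$values), ncol(ud$values))
  tab <- table((rc[ok, 2] - 1) * nrow(counts) + rc[ok, 1])
  counts[as.integer(names(tab))] <- as.integer(tab)
  mc <- counts / sum(counts)
  tv <- 0.5 * sum(abs(mc - ud$values))
  expect_lt(tv, 0.02)
})

test_that("doubling integration nodes barely moves the mass allocation", {
  set.seed(9)
  n <- 12
  traj <- mk_traj(cumsum(rnorm(n, 0, 250)), cumsum(rnorm(n, 0, 250)),
                  hourly_times(n))
  ud30 <- compute_ud(traj, bbmm_params(0.3, grid_resolution = 50,
                                       integration_points = 30))
  ud60 <- compute_ud(traj, bbmm_params(0.3, grid_resolution = 50,
                                       integration_points = 60))
  expect_lt(0.5 * sum(abs(ud30$values - ud60$values)), 1e-3)
})

test_that("long gaps are excluded from the UD with a log message", {
  tt <- utc("2021-06-01 00:00:00") + c(0, 3600, 3600 + 10 * 86400,
                                       2 * 3600 + 10 * 86400)
  traj <- mk_traj(c(0, 100, 5000, 5100), c(0, 0, 0, 0), tt, interval = 1)
  expect_message(
    ud <- compute_ud(traj, bbmm_params(0.1, grid_resolution = 25)),
    "excluding")
  # all mass near the two short bridges
  xs <- wolfmove:::raster_xcoords(ud)
  mass_far <- sum(ud$values[, xs > 2500])
  expect_equal(sum(ud$values), 1, tolerance = 1e-6)
  expect_gt(mass_far, 0.3)  # second short bridge keeps its share
})

test_that("isopleths: greedy mass bound, analytic disc area, monotonicity", {
  # symmetric circular Gaussian UD built directly
  sigma <- 300; res <- 20; half <- 1500
  xs <- seq(-half, half, by = res)
  g <- dnorm(xs, 0, sigma)
  v <- tcrossprod(g, g); v <- v / sum(v)
  ud <- wm_raster(v, -half - res / 2, -half - res / 2, res, "EPSG:32632")
  class(ud) <- c("wm_ud", class(ud))
  for (lev in c(0.5, 0.95)) {
    iso <- isopleth(ud, lev)
    expect_gte(iso$mass, lev)
    expect_lte(iso$mass, lev + max(ud$values))
    analytic <- pi * (-2 * log(1 - lev)) * sigma^2 / 1e6
    expect_lt(abs(iso$area_km2 - analytic) / analytic, 0.05)
  }
  areas <- vapply(c(0.5, 0.8, 0.95, 0.9999),
                  function(l) isopleth(ud, l)$area_km2, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_error(isopleth(ud, 1.2))
})

test_that("larger location error inflates the 95% isopleth area", {
  traj <- mk_traj(c(0, 150, 320, 400), c(0, 80, 20, 150), hourly_times(4))
  area_for <- function(delta) {
    ud <- compute_ud(traj, bbmm_params(0, delta = delta,
                                       grid_resolution = 10))
    isopleth(ud, 0.95)$area_km2
  }
  expect_gt(area_for(60), area_for(30))
})

test_that("main_component keeps the dominant region of a split isopleth", {
  # two Gaussian blobs, one holding ~2/3 of the mass
  res <- 20
  xs <- seq(-2000, 2000, by = res)
  g1 <- dnorm(xs, -1200, 150); g2 <- dnorm(xs, 1200, 150)
  v <- 2 * tcrossprod(g1, g1) + tcrossprod(g2, g2)
  v <- v / sum(v)
  ud <- wm_raster(v, min(xs) - res / 2, min(xs) - res / 2, res, "EPSG:32632")
  class(ud) <- c("wm_ud", class(ud))
  iso <- isopleth(ud, 0.95)
  mc <- main_component(iso, ud)
  expect_lt(mc$area_km2, iso$area_km2)
  expect_gt(mc$mass, 0.5)
  # the kept component is the heavier blob (x = -1200; matrix rows run
  # north-first, so that blob sits at northing +1200)
  expect_true(isopleth_contains(mc, -1200, 1200))
  expect_false(isopleth_contains(mc, 1200, -1200))
})
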