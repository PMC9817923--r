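# Spatio-temporal resting-site detection, merging, diurnality, filtering.

# Trajectory with rest bouts at given locations/durations separated by
# travel legs; hourly fixes.
bout_track <- function(bouts, t0 = utc("2021-06-21 06:00:00")) {
  xs <- numeric(0); ys <- numeric(0); tt <- numeric(0)
  cur <- as.numeric(t0)
  pos <- c(0, 0)
  for (b in bouts) {
    if (b$type == "move") {
      to <- b$to
      n <- b$hours
      xs <- c(xs, seq(pos[1], to[1], length.out = n + 1)[-1])
      ys <- c(ys, seq(pos[2], to[2], length.out = n + 1)[-1])
      tt <- c(tt, cur + 3600 * seq_len(n))
      cur <- cur + 3600 * n
      pos <- to
    } else {
      n <- b$hours
      xs <- c(xs, rep(b$at[1], n))
      ys <- c(ys, rep(b$at[2], n))
      tt <- c(tt, cur + 3600 * seq_len(n))
      cur <- cur + 3600 * n
      pos <- b$at
    }
  }
  mk_traj(xs, ys, as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
          interval = 1)
}

test_that("a six-hour dwell is a site and a 5 h 59 min dwell is not", {
  # 7 hourly fixes within 50 m span exactly 6 h -> one site
  set.seed(3)
  jit <- matrix(runif(14, -25, 25), ncol = 2)
  tr <- mk_traj(1000 + jit[, 1], 1000 + jit[, 2], hourly_times(7),
                interval = 1)
  s <- detect_resting_sites(tr)
  expect_equal(nrow(s), 1)
  expect_gte(s$duration_h, 6)
  expect_lt(sqrt((s$x - 1000)^2 + (s$y - 1000)^2), 50)

  # same dwell cut to 5 h 59 min, then a 2 km leap -> no site
  tt <- c(hourly_times(6), utc("2021-06-01 05:59:00"),
          utc("2021-06-01 07:00:00"))
  tr2 <- mk_traj(c(1000 + jit[1:6, 1], 1000, 3000),
                 c(1000 + jit[1:6, 2], 1000, 1000), tt, interval = 1)
  s2 <- detect_resting_sites(tr2)
  expect_equal(nrow(s2), 0)
})

test_that("consecutive nearby clusters merge; distant ones stay apart", {
  near <- bout_track(list(
    list(type = "rest", at = c(0, 0), hours = 7),
    list(type = "rest", at = c(400, 0), hours = 7),
    list(type = "move", to = c(5000, 0), hours = 5)))
  s <- detect_resting_sites(near)
  expect_equal(nrow(s), 1)                      # 400 m apart -> merged
  expect_true(s$x > 0 && s$x < 400)             # pooled centroid between them

  far <- bout_track(list(
    list(type = "rest", at = c(0, 0), hours = 7),
    list(type = "move", to = c(3000, 0), hours = 3),
    list(type = "rest", at = c(3000, 0), hours = 7),
    list(type = "move", to = c(9000, 0), hours = 5)))
  s2 <- detect_resting_sites(far)
  expect_equal(nrow(s2), 2)
  # retained sites never share a fix and all meet the duration rule
  expect_true(all(s2$duration_h >= 6))
  expect_lt(s2$last_fix[1], s2$first_fix[2])
})

test_that("detection is invariant to translating the coordinates", {
  tr <- bout_track(list(
    list(type = "rest", at = c(100, 200), hours = 8),
    list(type = "move", to = c(4000, 4000), hours = 6),
    list(type = "rest", at = c(4000, 4000), hours = 9),
    list(type = "move", to = c(8000, 0), hours = 6)))
  s <- detect_resting_sites(tr)
  tr2 <- wolfmove:::traj_like(
    transform(as.data.frame(tr), x = x + 12345, y = y - 6789), tr)
  s2 <- detect_resting_sites(tr2)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$x - 12345, s$x)
  expect_equal(s2$y + 6789, s$y)
  expect_equal(s2$duration_h, s$duration_h)
})

test_that("planted bouts are recovered with accurate centroids", {
  # three >= 6 h bouts and one 5-h decoy among travel legs
  tr <- bout_track(list(
    list(type = "rest", at = c(0, 0), hours = 8),
    list(type = "move", to = c(6000, 0), hours = 6),
    list(type = "rest", at = c(6000, 0), hours = 7),
    list(type = "move", to = c(6000, 7000), hours = 6),
    list(type = "rest", at = c(6000, 7000), hours = 5),   # decoy < 6 h
    list(type = "move", to = c(0, 7000), hours = 6),
    list(type = "rest", at = c(0, 7000), hours = 10),
    list(type = "move", to = c(-6000, 0), hours = 6)))
  s <- detect_resting_sites(tr)
  expect_equal(nrow(s), 3)
  planted <- rbind(c(0, 0), c(6000, 0), c(0, 7000))
  d <- apply(planted, 1, function(p) min(sqrt((s$x - p[1])^2 +
                                              (s$y - p[2])^2)))
  expect_true(all(d < 100))
})

test_that("gaps in the fix series break temporal contiguity", {
  # two 4-h dwells at the same spot separated by a 6-h hole: neither
  # qualifies on its own, and the hole prevents their union
  tt <- c(hourly_times(4), utc("2021-06-01 10:00:00") + 3600 * (0:3))
  tr <- mk_traj(rep(0, 8), rep(0, 8), tt, interval = 1)
  s <- detect_resting_sites(tr)
  expect_equal(nrow(s), 0)
})

test_that("diurnality integrates day over day-plus-night occupancy", {
  lat <- 45.2; lon <- 9.2
  # midsummer midday bout: fully diurnal
  expect_equal(diurnality(utc("2021-06-21 08:00:00"),
                          utc("2021-06-21 14:00:00"), lat, lon), 1)
  # dead-of-night bout: fully nocturnal
  expect_equal(diurnality(utc("2021-06-21 22:00:00"),
                          utc("2021-06-22 02:00:00"), lat, lon), 0)
  # bout spanning dusk: oracle from the solar transition times (uniroot)
  start <- utc("2021-06-21 15:00:00"); end <- utc("2021-06-21 23:00:00")
  f0 <- function(t) solar_elevation(as.POSIXct(t, origin = "1970-01-01",
                                               tz = "UTC"), lat, lon)
  sunset <- uniroot(f0, c(as.numeric(start), as.numeric(end)))$root
  night_start <- uniroot(function(t) f0(t) + 6,
                         c(as.numeric(start), as.numeric(end)))$root
  day_s <- sunset - as.numeric(start)
  night_s <- as.numeric(end) - night_start
  expected <- day_s / (day_s + night_s)
  expect_equal(diurnality(start, end, lat, lon), expected, tolerance = 0.01)
})

test_that("sites gain phase, elevation and plain/dispersal filtering", {
  tr <- bout_track(list(
    list(type = "rest", at = c(600500, 5000500), hours = 8),
    list(type = "move", to = c(600500, 5001500), hours = 4),
    list(type = "rest", at = c(600500, 5001500), hours = 8),
    list(type = "move", to = c(601500, 5001500), hours = 4),
    list(type = "rest", at = c(601500, 5001500), hours = 8),
    list(type = "move", to = c(601900, 5000100), hours = 4)))
  ls <- tiny_landscape()
  n <- nrow(tr)
  labels <- rep("dispersal", n)
  labels[seq_len(9)] <- "settlement"
  phases <- wolfmove:::build_phases(tr, labels, rep(FALSE, n))
  s <- detect_resting_sites(tr, phases = phases, elevation = ls$elevation)
  expect_equal(nrow(s), 3)
  expect_equal(s$phase[1], "settlement")
  # the elevation ramp runs 400 m (north) to 100 m (south)
  expect_true(all(is.finite(s$elev_m)))
  kept <- filter_dispersal_plain(s)
  expect_true(all(kept$phase %in% c("pre_dispersal", "dispersal")))
  expect_true(all(kept$elev_m < 300))
  expect_lt(nrow(kept), nrow(s))
})
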