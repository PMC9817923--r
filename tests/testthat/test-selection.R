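# Choice sets, covariate extraction, conditional logistic regression,
# radius selection, correlation filtering, dredging.

test_that("covariates at characteristic locations match closed forms", {
  ls <- tiny_landscape()
  x0 <- ls$landcover$xmin; y0 <- ls$landcover$ymin
  # deep inside the homogeneous tree block: density 1 at small radii
  cv <- extract_covariates(c(x0 + 250, y0 + 1000), ls,
                           radii_density = c(50, 100), radii_metrics = 250)
  expect_equal(cv$tree_density_50, 1)
  expect_equal(cv$tree_density_100, 1)
  expect_equal(cv$settlement_density_50, 0)
  expect_equal(cv$decay_dist_tree, 0)   # standing in the class

  # on the motorway (y0 + 500): decayed distance is 0
  on_mw <- extract_covariates(c(x0 + 1000, y0 + 500), ls,
                              radii_density = 50, radii_metrics = 250)
  expect_equal(on_mw$decay_dist_motorway, 0)
})

test_that("exponential decay of line distance follows 1 - exp(-d/scale)", {
  ls <- tiny_landscape()
  x0 <- ls$landcover$xmin; y0 <- ls$landcover$ymin
  # river is the vertical line x = x0 + 1500
  for (d in c(250, 500, 1000)) {
    cv <- extract_covariates(c(x0 + 1500 - d, y0 + 1000), ls,
                             radii_density = 50, radii_metrics = 250,
                             decay_scale = 500)
    expect_equal(cv$decay_dist_river, 1 - exp(-d / 500), tolerance = 1e-9)
  }
})

test_that("patch density counts 8-connected mosaic patches per km2", {
  # two diagonal blobs of one class in an open matrix: diagonal contact
  # joins them under 8-connectivity
  v <- matrix(0L, 40, 40)
  v[10:14, 10:14] <- 1L
  v[15:19, 15:19] <- 1L     # touches the first at a corner
  v[30:32, 30:32] <- 2L     # separate class elsewhere
  r <- wm_raster(v, 0, 0, 10, "EPSG:32632")
  # buffer covering everything: patches = 1 (tree, merged) + 1 (class 2)
  # + 1 (open background)
  pd <- raster_patch_density(r, 200, 200, 280)
  area <- pi * 280^2 / 1e6
  expect_equal(pd, 3 / area)
  # label counter agrees with hand-countable fixtures
  expect_equal(wolfmove:::count_patches_8(v == 1L), 1)
  expect_equal(wolfmove:::count_patches_8(diag(5) > 0), 1)
  # corner contact joins under 8-connectivity; a full empty column separates
  expect_equal(wolfmove:::count_patches_8(matrix(c(TRUE, FALSE, FALSE, TRUE,
                                                   FALSE, FALSE), 2)), 1)
  expect_equal(wolfmove:::count_patches_8(matrix(c(TRUE, FALSE, FALSE, FALSE,
                                                   FALSE, TRUE), 2)), 2)
})

mk_sites_df <- function(traj, at_fix) {
  data.frame(site_id = seq_along(at_fix),
             x = traj$x[at_fix], y = traj$y[at_fix],
             start_time = traj$timestamp[at_fix],
             first_fix = at_fix, last_fix = at_fix)
}

test_that("choice sets hold 1 used + 25 available and are seed-stable", {
  ls <- tiny_landscape()
  x0 <- ls$landcover$xmin; y0 <- ls$landcover$ymin
  set.seed(2)
  n <- 40
  traj <- mk_traj(x0 + 1000 + cumsum(rnorm(n, 0, 60)),
                  y0 + 1000 + cumsum(rnorm(n, 0, 60)), hourly_times(n))
  sites <- mk_sites_df(traj, c(15, 30))
  cs1 <- suppressMessages(build_choice_sets(sites, traj, ls, seed = 9))
  expect_length(cs1, 2)
  expect_equal(nrow(cs1[[1]]$xy), 26)
  expect_equal(cs1[[1]]$used, 1L)
  expect_equal(cs1[[1]]$xy[1, ], c(sites$x[1], sites$y[1]))
  cs2 <- suppressMessages(build_choice_sets(sites, traj, ls, seed = 9))
  expect_identical(cs1[[1]]$xy, cs2[[1]]$xy)
  cs3 <- suppressMessages(build_choice_sets(sites, traj, ls, seed = 10))
  expect_false(identical(cs1[[1]]$xy, cs3[[1]]$xy))

  # a site at the first fix has no previous fix: stratum skipped
  sites0 <- mk_sites_df(traj, c(1, 30))
  expect_message(cs0 <- build_choice_sets(sites0, traj, ls, seed = 1),
                 "skipped")
  expect_length(cs0, 1)
})

test_that("degenerate step distributions put availability on a circle", {
  ls <- tiny_landscape()
  x0 <- ls$landcover$xmin; y0 <- ls$landcover$ymin
  # constant step length 100 m, constant 90-degree turns
  n <- 30
  ang <- cumsum(rep(pi / 2, n))
  traj <- mk_traj(x0 + 1000 + cumsum(100 * cos(ang)),
                  y0 + 1000 + cumsum(100 * sin(ang)), hourly_times(n))
  sites <- mk_sites_df(traj, 20)
  cs <- suppressMessages(build_choice_sets(sites, traj, ls, seed = 4))
  prev <- cs[[1]]$previous_fix
  rad <- sqrt((cs[[1]]$xy[-1, 1] - traj$x[prev])^2 +
              (cs[[1]]$xy[-1, 2] - traj$y[prev])^2)
  expect_equal(rad, rep(100, 25), tolerance = 1e-9)
})

test_that("tiny-instance CLR matches a brute-force grid oracle", {
  set.seed(6)
  strata <- lapply(1:2, function(s) {
    matrix(rnorm(26), ncol = 1, dimnames = list(NULL, "x"))
  })
  fit <- fit_clr(strata, standardize = FALSE)
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, function(b) {
    sum(vapply(strata, function(m) {
      m[1, 1] * b - log(sum(exp(m[, 1] * b)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
})

test_that("an uninformative covariate fits to exactly zero", {
  m <- matrix(rep(1, 26), ncol = 1, dimnames = list(NULL, "b"))
  expect_error(fit_clr(list(m), standardize = FALSE), "constant")
  # equal in used and available within strata but varying across strata
  strata <- lapply(1:4, function(s) matrix(rep(s, 26), ncol = 1,
                                           dimnames = list(NULL, "b")))
  fit <- fit_clr(strata, standardize = FALSE)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-10)
})

test_that("CLR recovers known coefficients and agrees with survival", {
  beta <- c(x1 = 1.0, x2 = -1.5, x3 = 0.5)
  strata <- simulate_clr_strata(200, beta, seed = 17)
  fit <- fit_clr(strata, standardize = FALSE)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta - beta) <= 2 * fit$se))
  expect_equal(unname(fit$aic), -2 * fit$loglik + 2 * 3)
  expect_equal(fit$ci90[, "hi"] - fit$beta, qnorm(0.95) * fit$se,
               ignore_attr = TRUE)

  skip_if_not_installed("survival")
  # one event per stratum: the stratified Cox partial likelihood equals the
  # conditional logistic likelihood exactly
  df <- do.call(rbind, lapply(seq_along(strata), function(i) {
    data.frame(strata[[i]], used = c(1, rep(0, 25)), stratum = i)
  }))
  cl <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), df$used) ~ x1 + x2 + x3 +
      survival::strata(stratum), data = df)
  expect_equal(unname(fit$beta), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cl)))), tolerance = 1e-5)
  expect_equal(fit$loglik, cl$loglik[2], tolerance = 1e-8)
})

test_that("the conditional likelihood ignores stratum-constant shifts", {
  beta <- c(x1 = 0.8)
  strata <- simulate_clr_strata(40, beta, seed = 3)
  fit <- fit_clr(strata, standardize = FALSE)
  shifted <- lapply(seq_along(strata), function(i) strata[[i]] + 5 * i)
  fit2 <- fit_clr(shifted, standardize = FALSE)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-8)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-6)
})

test_that("correlation filter drops the more redundant of each pair", {
  set.seed(12)
  n <- 300
  z <- rnorm(n)
  m <- cbind(a = z + rnorm(n, 0, 0.2),       # a, b, c mutually correlated
             b = z + rnorm(n, 0, 0.2),
             c = z + rnorm(n, 0, 0.2),
             d = rnorm(n))                   # independent
  kept <- correlation_filter(m, threshold = 0.7)
  expect_equal(sum(c("a", "b", "c") %in% kept), 1)  # exactly one survives
  expect_true("d" %in% kept)

  # orthogonal covariates: everything retained
  m2 <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_setequal(correlation_filter(m2), c("a", "b", "c"))

  # constant covariate dropped with a warning
  m3 <- cbind(a = rnorm(n), k = rep(1, n), b = rnorm(n))
  expect_warning(kept3 <- correlation_filter(m3), "constant")
  expect_setequal(kept3, c("a", "b"))
})

# strata whose radius covariates share a common factor but only radius "50"
# drives the choice
radius_strata <- function(n_strata, seed, gen_col = "tree_density_50") {
  set.seed(seed)
  cols <- paste0("tree_density_", c(50, 100, 250, 500))
  lapply(seq_len(n_strata), function(s) {
    common <- rnorm(26)
    X <- vapply(cols, function(cl) common + rnorm(26, 0, 0.8),
                numeric(26))
    colnames(X) <- cols
    u <- 1.5 * X[, gen_col]
    p <- exp(u - max(u)); p <- p / sum(p)
    used <- sample.int(26, 1, prob = p)
    X[c(used, setdiff(1:26, used)), , drop = FALSE]
  })
}

test_that("preliminary model selection finds the generating radius", {
  hits <- vapply(1:20, function(r) {
    strata <- radius_strata(60, seed = 400 + r)
    select_radius(strata, "tree_density")$radius == 50
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("radius selection tie-breaks and degenerate inputs", {
  # identical covariate at all radii: the smaller radius wins the tie
  strata <- radius_strata(30, seed = 1)
  same <- lapply(strata, function(m) {
    m[] <- m[, 1]
    m
  })
  expect_equal(select_radius(same, "tree_density")$radius, 50)
  # single radius supplied: returned unchanged
  one <- lapply(strata, function(m) m[, "tree_density_250", drop = FALSE])
  expect_equal(select_radius(one, "tree_density")$radius, 250)
  expect_error(select_radius(strata, "no_such"), "no columns")
})

test_that("dredge weighting follows the closed-form Akaike weights", {
  aw <- aic_weights(c(100, 101, 104), delta_aic = 2)
  expect_equal(aw$retained, c(1L, 2L))
  expect_equal(aw$weights, exp(c(0, -0.5)) / sum(exp(c(0, -0.5))))
  # equal-AIC pair splits evenly
  aw2 <- aic_weights(c(50, 50, 60))
  expect_equal(aw2$weights, c(0.5, 0.5))
})

test_that("dredging averages, bounds importance, handles dominance", {
  beta <- c(x1 = 2, x2 = 0)
  strata <- simulate_clr_strata(150, beta, seed = 23)
  dr <- suppressMessages(dredge_average(strata, c("x1", "x2")))
  expect_equal(nrow(dr$table), 4)  # null, x1, x2, x1+x2
  w <- dr$table$weight[!is.na(dr$table$weight)]
  expect_equal(sum(w), 1)
  expect_true(all(dr$relative_importance >= 0 &
                  dr$relative_importance <= 1))
  expect_gt(dr$relative_importance["x1"], 0.9)
  # single retained model: the average equals that model's coefficients
  if (length(dr$retained) == 1) {
    best_terms <- strsplit(dr$retained, "\\+")[[1]]
    refit <- fit_clr(strata, covariates = best_terms)
    expect_equal(dr$full_average_beta[best_terms], refit$beta[best_terms])
  }
})

test_that("null-model likelihood anchors the dredge table", {
  strata <- simulate_clr_strata(50, c(x1 = 0.001), seed = 5)
  dr <- dredge_average(strata, "x1")
  null_row <- dr$table[dr$table$model == "(null)", ]
  expect_equal(null_row$loglik, -50 * log(26))
  expect_equal(null_row$k, 0)
})
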