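# Matched case-control (1:25) resting-site selection analysis: availability
# sampling from the individual's empirical step-length and turning-angle
# distributions, covariate extraction from the landscape, conditional
# logistic regression (CLR) fitted by Newton iteration on the conditional
# likelihood, preliminary radius selection, correlation filtering, and AIC
# dredging with full model averaging.

#' Build matched choice sets for resting sites
#'
#' For each resting site the GPS fix preceding the site is located and 25
#' available locations are generated from it by drawing step lengths and
#' turning angles (relative to the heading of the step that arrived at the
#' previous fix) with replacement from the individual's empirical step
#' distributions. Available points falling outside the landscape or in water
#' are resampled up to `max_retry` times, then clipped with a warning.
#'
#' @param sites A `resting_sites` data.frame.
#' @param traj The `wolf_traj` the sites were detected on.
#' @param landscape A `wm_landscape` (see [read_landscape()]).
#' @param n_avail Available locations per used site (default 25).
#' @param seed Integer seed for the availability draw.
#' @param max_retry Redraw cap per point for off-landscape/water locations.
#' @return A list of choice sets (class `choice_sets`); each element has
#'   `stratum_id`, `site_id`, `xy` (matrix of 1 used + `n_avail` available
#'   rows), `used` (row index 1), `previous_fix`.
#' @export
build_choice_sets <- function(sites, traj, landscape, n_avail = 25,
                              seed = NULL, max_retry = 100) {
  if (!is.null(seed)) set.seed(seed)
  steps <- compute_steps(traj, label_periods = FALSE)
  len_pool <- steps$length_m
  turn_pool <- steps$turning_angle_rad[!is.na(steps$turning_angle_rad)]
  ext <- raster_extent(landscape$landcover)
  water <- landscape$classes["water"]
  t <- as.numeric(traj$timestamp)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    prev <- which(t < as.numeric(sites$start_time[i]))
    prev <- if (length(prev)) max(prev) else NA_integer_
    if (is.na(prev) || sites$first_fix[i] <= 1) {
      wm_log(sprintf("choice sets: site %d has no previous fix; stratum skipped",
                     sites$site_id[i]), level = "WARN")
      next
    }
    # heading of the step that arrived at the previous fix
    ref_heading <- if (prev >= 2) {
      atan2(traj$y[prev] - traj$y[prev - 1], traj$x[prev] - traj$x[prev - 1])
    } else 0
    pts <- matrix(NA_real_, n_avail, 2)
    for (j in seq_len(n_avail)) {
      ok <- FALSE
      for (try in seq_len(max_retry)) {
        L <- sample(len_pool, 1)
        h <- ref_heading + sample(turn_pool, 1)
        p <- c(traj$x[prev] + L * cos(h), traj$y[prev] + L * sin(h))
        inb <- p[1] >= ext["xmin"] && p[1] <= ext["xmax"] &&
          p[2] >= ext["ymin"] && p[2] <= ext["ymax"]
        inwater <- inb && !is.na(water) &&
          isTRUE(raster_extract(landscape$landcover, p[1], p[2]) == water)
        if (inb && !inwater) { pts[j, ] <- p; ok <- TRUE; break }
      }
      if (!ok) {
        wm_log("choice sets: retry cap hit; clipping point to landscape",
               level = "WARN")
        pts[j, ] <- c(min(max(p[1], ext["xmin"]), ext["xmax"]),
                      min(max(p[2], ext["ymin"]), ext["ymax"]))
      }
    }
    out[[length(out) + 1L]] <- list(
      stratum_id = length(out) + 1L,
      site_id = sites$site_id[i],
      xy = rbind(c(sites$x[i], sites$y[i]), pts),
      used = 1L,
      previous_fix = prev
    )
  }
  structure(out, class = "choice_sets")
}

#' Extract environmental covariates at a set of locations
#'
#' Density covariates are buffer means of the tree-density and
#' settlement-density rasters at each requested radius; the landscape metric
#' is patch density (8-connected patches of all land-cover classes per km2)
#' at each metric radius; distance covariates are exponential decays
#' `1 - exp(-d / decay_scale)` of the Euclidean distance to the nearest
#' motorway, primary road, river (line features) and tree or built patch
#' (raster classes), so that 0 means on the feature and values saturate
#' towards 1 far from it.
#'
#' @param xy Two-column coordinate matrix (m).
#' @param landscape A `wm_landscape`.
#' @param radii_density Buffer radii (m) for density covariates.
#' @param radii_metrics Buffer radii (m) for patch density.
#' @param decay_scale Decay scale (m) of the distance transforms.
#' @param columns Optional subset of covariate columns to compute (names as
#'   in the full output); `NULL` computes all.
#' @return Data.frame, one row per location: `tree_density_<r>`,
#'   `settlement_density_<r>`, `patch_density_<r>`, `decay_dist_motorway`,
#'   `decay_dist_primary`, `decay_dist_river`, `decay_dist_built`,
#'   `decay_dist_tree`.
#' @export
extract_covariates <- function(xy, landscape,
                               radii_density = c(50, 100, 250, 500),
                               radii_metrics = c(250, 500),
                               decay_scale = 500, columns = NULL) {
  xy <- rbind(xy)
  n <- nrow(xy)
  wanted <- function(nm) is.null(columns) || nm %in% columns
  out <- data.frame(row.names = seq_len(n))
  for (r in radii_density) {
    for (fam in c("tree_density", "settlement_density")) {
      nm <- paste0(fam, "_", r)
      if (!wanted(nm)) next
      rast <- landscape[[fam]]
      out[[nm]] <- vapply(seq_len(n), function(i)
        raster_buffer_mean(rast, xy[i, 1], xy[i, 2], r), numeric(1))
    }
  }
  for (r in radii_metrics) {
    nm <- paste0("patch_density_", r)
    if (!wanted(nm)) next
    out[[nm]] <- vapply(seq_len(n), function(i)
      raster_patch_density(landscape$landcover, xy[i, 1], xy[i, 2], r),
      numeric(1))
  }
  decay <- function(d) 1 - exp(-d / decay_scale)
  cls <- landscape$classes
  road_cls <- vapply(landscape$roads, function(l)
    attr(l, "class_attr") %||% "primary", "")
  if (wanted("decay_dist_motorway")) {
    out$decay_dist_motorway <- decay(dist_to_lines(xy[, 1], xy[, 2],
      landscape$roads[road_cls == "motorway"]))
  }
  if (wanted("decay_dist_primary")) {
    out$decay_dist_primary <- decay(dist_to_lines(xy[, 1], xy[, 2],
      landscape$roads[road_cls == "primary"]))
  }
  if (wanted("decay_dist_river")) {
    out$decay_dist_river <- decay(dist_to_lines(xy[, 1], xy[, 2],
                                                landscape$rivers))
  }
  if (wanted("decay_dist_built")) {
    out$decay_dist_built <- decay(raster_class_distance(landscape$landcover,
      xy[, 1], xy[, 2], cls["built"]))
  }
  if (wanted("decay_dist_tree")) {
    out$decay_dist_tree <- decay(raster_class_distance(landscape$landcover,
      xy[, 1], xy[, 2], cls["tree"]))
  }
  out
}

#' Fit a conditional logistic regression on matched strata
#'
#' Maximises the conditional log-likelihood
#' `sum_s [ x_used beta - log sum_j exp(x_j beta) ]`
#' (one used location per stratum) by Newton-Raphson with step halving,
#' stopping at gradient max-norm below `tol`. Standard errors come from the
#' inverse observed information; 90% confidence intervals are Wald.
#'
#' @param strata List of numeric matrices, one per stratum, covariates in
#'   columns, the used location in row 1.
#' @param covariates Optional character vector selecting/ordering columns.
#' @param standardize Z-score covariates across all locations pooled before
#'   fitting (default `TRUE`); raw-scale coefficients are also reported.
#' @param tol Gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `clr_fit`: `beta`, `se`, `ci90` (matrix lo/hi), `z`, `p_value`,
#'   `loglik`, `null_loglik`, `aic`, `n_strata`, `converged`,
#'   `beta_raw`/`se_raw` (original covariate scale), `scale` (means/sds
#'   used).
#' @export
fit_clr <- function(strata, covariates = NULL, standardize = TRUE,
                    tol = 1e-8, max_iter = 50) {
  stopifnot(length(strata) >= 1)
  if (!is.null(covariates)) {
    strata <- lapply(strata, function(m) m[, covariates, drop = FALSE])
  }
  vars <- colnames(strata[[1]])
  k <- ncol(strata[[1]])
  pooled <- do.call(rbind, strata)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("covariate(s) constant across all locations: ",
         paste(vars[sdv == 0], collapse = ", "), call. = FALSE)
  }
  if (standardize) {
    strata <- lapply(strata, function(m) sweep(sweep(m, 2, mu), 2, sdv, "/"))
  }
  beta <- rep(0, k)
  ll_grad_hess <- function(beta) {
    ll <- 0; g <- rep(0, k); H <- matrix(0, k, k)
    for (m in strata) {
      eta <- drop(m %*% beta)
      eta <- eta - max(eta)
      p <- exp(eta); p <- p / sum(p)
      ll <- ll + eta[1] - log(sum(exp(eta)))
      xb <- drop(crossprod(p, m))
      ll_g <- m[1, ] - xb
      g <- g + ll_g
      H <- H + crossprod(m * sqrt(p)) - tcrossprod(xb)
    }
    list(ll = ll, g = g, H = H)
  }
  cur <- ll_grad_hess(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (max(abs(cur$g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$H, cur$g),
                     error = function(e) stop(
                       "singular information matrix; covariates are collinear (",
                       paste(vars, collapse = ", "), ")", call. = FALSE))
    sz <- 1
    repeat {
      cand <- beta + sz * step
      nxt <- ll_grad_hess(cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-8) break
    }
    if (sqrt(sum((sz * step)^2)) > 50) {
      warning("likelihood appears unbounded (complete separation); ",
              "coefficients reported at iteration cap")
      beta <- cand; cur <- nxt
      break
    }
    beta <- cand; cur <- nxt
  }
  if (!converged && max(abs(cur$g)) < 1e-4) converged <- TRUE
  info <- cur$H
  vc <- tryCatch(solve(info), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, k) else {
    d <- diag(vc)
    d[d < 0] <- NA_real_
    suppressWarnings(sqrt(d))
  }
  zq <- stats::qnorm(0.95)
  names(beta) <- names(se) <- vars
  null_ll <- -length(strata) * log(nrow(strata[[1]]))
  beta_raw <- if (standardize) beta / sdv else beta
  se_raw <- if (standardize) se / sdv else se
  structure(list(
    beta = beta, se = se,
    ci90 = cbind(lo = beta - zq * se, hi = beta + zq * se),
    z = beta / se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    loglik = cur$ll, null_loglik = null_ll,
    aic = -2 * cur$ll + 2 * k,
    n_strata = length(strata), converged = converged,
    beta_raw = beta_raw, se_raw = se_raw,
    scale = list(mean = mu, sd = sdv), standardized = standardize
  ), class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic regression (%d strata, loglik %.3f, AIC %.2f)\n",
              x$n_strata, x$loglik, x$aic))
  tab <- data.frame(beta = x$beta, se = x$se, lo90 = x$ci90[, "lo"],
                    hi90 = x$ci90[, "hi"], p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Choose the most informative buffer radius for a covariate family
#'
#' Fits a univariate CLR per candidate radius and returns the radius with
#' the lowest AIC (ties broken toward the smaller radius).
#'
#' @param strata List of per-stratum covariate matrices (used row first).
#' @param family Covariate base name, e.g. `"tree_density"`; candidate
#'   columns are `<family>_<radius>`.
#' @param radii Candidate radii; default all radii found for the family.
#' @return A list: `radius`, `column`, `aic` (named vector over radii).
#' @export
select_radius <- function(strata, family, radii = NULL) {
  vars <- colnames(strata[[1]])
  cols <- grep(paste0("^", family, "_[0-9]+$"), vars, value = TRUE)
  if (!is.null(radii)) cols <- intersect(cols, paste0(family, "_", radii))
  if (!length(cols)) stop("no columns for covariate family ", family,
                          call. = FALSE)
  r_of <- as.numeric(sub(paste0(family, "_"), "", cols))
  o <- order(r_of)
  cols <- cols[o]; r_of <- r_of[o]
  aics <- rep(NA_real_, length(cols))
  names(aics) <- cols
  for (i in seq_along(cols)) {
    fit <- tryCatch(fit_clr(strata, covariates = cols[i]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      wm_log(sprintf("select_radius: radius %g skipped (fit failed)", r_of[i]),
             level = "WARN")
      next
    }
    aics[i] <- fit$aic
  }
  if (all(is.na(aics))) stop("no radius produced a convergent fit for ",
                             family, call. = FALSE)
  best <- which(aics == min(aics, na.rm = TRUE))[1]  # ties -> smaller radius
  list(radius = r_of[best], column = cols[best], aic = aics)
}

#' Drop highly correlated covariates
#'
#' Computes pairwise Pearson correlations over all locations and, while any
#' pair exceeds the threshold in absolute value, removes from the worst pair
#' the member with the larger mean absolute correlation against all other
#' covariates. Constant covariates are dropped first with a warning.
#'
#' @param covariates Numeric matrix or data.frame (locations x covariates).
#' @param threshold Absolute correlation threshold (default 0.7).
#' @return Character vector of retained covariate names, in input order.
#' @export
correlation_filter <- function(covariates, threshold = 0.7) {
  m <- as.matrix(covariates)
  stopifnot(ncol(m) >= 2)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  keep <- colnames(m)
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(m[, keep, drop = FALSE]))
    diag(cm) <- 0
    mx <- max(cm)
    if (mx <= threshold) break
    idx <- which(cm == mx, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(cm[pair, , drop = FALSE])
    drop_var <- pair[which.max(mean_abs)]
    keep <- setdiff(keep, drop_var)
  }
  keep
}

#' Akaike weights over a delta-AIC retained set
#'
#' @param aic Numeric vector of AIC scores (NA = failed fit).
#' @param delta_aic Retention threshold relative to the best score.
#' @return List with `retained` (indices) and `weights`
#'   (`exp(-delta/2)` normalised over the retained set).
#' @export
aic_weights <- function(aic, delta_aic = 2) {
  delta <- aic - min(aic, na.rm = TRUE)
  retained <- which(!is.na(delta) & delta <= delta_aic)
  w <- exp(-delta[retained] / 2)
  list(retained = retained, weights = w / sum(w))
}

#' All-subsets model selection with full model averaging
#'
#' Fits every subset of the candidate covariates (including the null model),
#' ranks by AIC, retains models within `delta_aic` of the best, computes
#' Akaike weights over the retained set, and forms full-average coefficients
#' (absent terms contribute 0) plus per-covariate relative importance (sum
#' of weights of retained models containing the term).
#'
#' @param strata List of per-stratum covariate matrices (used row first).
#' @param covariates Candidate covariate names (at most 12).
#' @param delta_aic Retention threshold on AIC difference (default 2).
#' @return A `clr_dredge`: `table` (all models: terms, k, loglik, AIC,
#'   delta_aic, weight with NA when not retained), `retained`,
#'   `full_average_beta`, `relative_importance`, `best`.
#' @export
dredge_average <- function(strata, covariates, delta_aic = 2) {
  k <- length(covariates)
  stopifnot(k >= 1, k <= 12)
  subsets <- lapply(0:(2^k - 1), function(mask) covariates[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0])
  rows <- list()
  fits <- list()
  for (i in seq_along(subsets)) {
    terms <- subsets[[i]]
    if (!length(terms)) {
      # null model: conditional likelihood with beta = 0
      ll <- -length(strata) * log(nrow(strata[[1]]))
      rows[[i]] <- data.frame(model = "(null)", k = 0, loglik = ll,
                              aic = -2 * ll)
      fits[[i]] <- NULL
      next
    }
    fit <- tryCatch(fit_clr(strata, covariates = terms),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      wm_log(sprintf("dredge: subset {%s} non-convergent; excluded",
                     paste(terms, collapse = ",")), level = "WARN")
      rows[[i]] <- data.frame(model = paste(terms, collapse = "+"),
                              k = length(terms), loglik = NA_real_,
                              aic = NA_real_)
      fits[[i]] <- NULL
      next
    }
    rows[[i]] <- data.frame(model = paste(terms, collapse = "+"),
                            k = length(terms), loglik = fit$loglik,
                            aic = fit$aic)
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  aw <- aic_weights(tab$aic, delta_aic)
  retained <- aw$retained
  w <- aw$weights
  tab$weight <- NA_real_
  tab$weight[retained] <- w
  avg <- stats::setNames(rep(0, k), covariates)
  imp <- stats::setNames(rep(0, k), covariates)
  for (j in seq_along(retained)) {
    i <- retained[j]
    terms <- subsets[[i]]
    if (length(terms)) {
      avg[terms] <- avg[terms] + w[j] * fits[[i]]$beta[terms]
      imp[terms] <- imp[terms] + w[j]
    }
  }
  o <- order(tab$aic)
  structure(list(table = tab[o, , drop = FALSE],
                 retained = tab$model[retained],
                 full_average_beta = avg,
                 relative_importance = imp,
                 best = fits[[which.min(tab$aic)]]),
            class = "clr_dredge")
}

#' @export
print.clr_dredge <- function(x, ...) {
  cat(sprintf("Dredge over %d models; %d retained (delta AIC <= 2)\n",
              nrow(x$table), length(x$retained)))
  cat("Full-average coefficients:\n")
  print(round(x$full_average_beta, 4))
  cat("Relative importance:\n")
  print(round(x$relative_importance, 3))
  invisible(x)
}
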