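# Pipeline orchestration: a YAML run configuration drives the stages
# simulate -> ud -> segment -> steps -> rest -> select, each writing its
# artifacts plus a machine-readable manifest into the run directory.

#' Default run configuration
#'
#' All stage parameters with their reference values: 30 m BBMM location
#' error, 100 m UD grid, 95% isopleth, 12 h / 6 day segmentation rules,
#' 10,000 permutations, 250 m / 6 h / 500 m resting-site rules, 1:25
#' availability with radii 50/100/250/500 m (densities) and 250/500 m
#' (patch density), 500 m decay scale, and delta-AIC 2 for model retention.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    crs = "EPSG:32632",
    fix_interval_h = 4,
    anchor_hours = NULL,      # NULL: seq(0, 23, fix_interval_h)
    tolerance_min = 10,
    bbmm = list(delta = 30, grid_resolution = 100, integration_points = 30,
                max_gap_days = 7, level = 0.95),
    segmentation = list(exploration_min_h = 12, predispersal_min_days = 6,
                        post_release_min_days = 2, buffer_m = 0),
    stats = list(n_perm = 10000),
    resting = list(radius = 250, min_hours = 6, merge_dist = 500,
                   max_elev = 300),
    selection = list(n_avail = 25, radii_density = c(50, 100, 250, 500),
                     radii_metrics = c(250, 500), decay_scale = 500,
                     cor_threshold = 0.7, delta_aic = 2),
    simulate = list()         # sim_config() overrides
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Values in the file override [default_config()]; everything else keeps its
#' default. Parameters are validated against stage preconditions.
#'
#' @param path YAML file.
#' @param seed Optional seed override.
#' @return A `run_config`.
#' @export
load_config <- function(path, seed = NULL) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, usr)
  if (!is.null(seed)) cfg$seed <- seed
  stopifnot(cfg$fix_interval_h > 0, cfg$bbmm$delta > 0,
            cfg$bbmm$grid_resolution > 0,
            cfg$bbmm$level > 0, cfg$bbmm$level < 1,
            cfg$resting$radius > 0, cfg$resting$min_hours > 0,
            cfg$selection$n_avail >= 1, cfg$stats$n_perm >= 1)
  class(cfg) <- "run_config"
  cfg
}

write_manifest <- function(outdir, stage, cfg, extra = list()) {
  man <- c(list(stage = stage, package_version = as.character(
    utils::packageVersion("wolfmove")),
    seed = cfg$seed, config_hash = config_hash(unclass(cfg))), extra)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(outdir, paste0("manifest_", stage, ".json")))
}

#' Simulate a dataset onto disk
#'
#' Generates a landscape and a collared wolf under the run configuration's
#' `simulate` settings (seeded by the run seed) and writes the same formats
#' the reading stages consume: `track.csv` (timestamp/longitude/latitude),
#' a landscape bundle directory, and `truth.json` with the generating phase
#' labels, planted resting bouts and selection coefficients.
#'
#' @param cfg A `run_config`.
#' @param outdir Output directory (created).
#' @return Invisibly, the `sim_wolf` object.
#' @export
run_simulate <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_args <- cfg$simulate
  if (!is.null(sim_args$phase_schedule)) {
    sim_args$phase_schedule <- as.data.frame(sim_args$phase_schedule)
  }
  sc <- do.call(sim_config, c(list(seed = cfg$seed), sim_args))
  sw <- simulate_wolf(sc)
  ll <- xy_to_lonlat(sw$traj$x, sw$traj$y, sc$crs)
  utils::write.csv(data.frame(
    timestamp = format(sw$traj$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    longitude = sprintf("%.8f", ll[, 1]), latitude = sprintf("%.8f", ll[, 2])
  ), file.path(outdir, "track.csv"), row.names = FALSE, quote = FALSE)
  write_landscape(sw$landscape, file.path(outdir, "landscape"))
  truth <- list(
    individual_id = attr(sw$traj, "individual_id"),
    phase = sw$truth$phase,
    true_beta = as.list(sw$truth$true_beta),
    release = sw$truth$release,
    rest_sites = if (is.null(sw$truth$rest_sites)) list() else
      within(sw$truth$rest_sites, {
        start_time <- format(start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
        end_time <- format(end_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      })
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(outdir, "truth.json"))
  write_manifest(outdir, "simulate", cfg)
  invisible(sw)
}

load_traj <- function(cfg, outdir) {
  track_path <- file.path(outdir, "track.csv")
  if (!file.exists(track_path)) {
    stop("missing ", track_path, "; run the simulate stage (or supply a track) first",
         call. = FALSE)
  }
  tr <- read_track(track_path, id = "wolf")
  traj <- project_track(tr, cfg$crs)
  regularize(traj, cfg$fix_interval_h,
             anchor_hours = cfg$anchor_hours %||% seq(0, 23, by = cfg$fix_interval_h),
             tolerance_min = cfg$tolerance_min)
}

#' Estimate the utilisation distribution stage
#'
#' Reads the track, regularises it, estimates the Brownian motion variance,
#' computes the BBMM UD and the 95% isopleth, and writes `ud.asc`,
#' `isopleth.geojson` (full isopleth) and `settlement.geojson` (main
#' connected component) with `area_km2` properties.
#'
#' @param cfg A `run_config`.
#' @param outdir Run directory holding the upstream artifacts.
#' @return Invisibly, a list with `ud`, `iso`, `settlement`, `sigma2_m`.
#' @export
run_ud <- function(cfg, outdir) {
  traj <- load_traj(cfg, outdir)
  s2 <- estimate_sigma2m(traj, delta = cfg$bbmm$delta)
  params <- bbmm_params(sigma2_m = s2, delta = cfg$bbmm$delta,
                        grid_resolution = cfg$bbmm$grid_resolution,
                        integration_points = cfg$bbmm$integration_points,
                        max_gap_days = cfg$bbmm$max_gap_days)
  ud <- compute_ud(traj, params)
  iso <- isopleth(ud, cfg$bbmm$level)
  settlement <- main_component(iso, ud)
  write_ud_raster(ud, file.path(outdir, "ud.asc"))
  write_isopleth(iso, file.path(outdir, "isopleth.geojson"))
  write_isopleth(settlement, file.path(outdir, "settlement.geojson"))
  write_manifest(outdir, "ud", cfg, list(sigma2_m = s2,
                                         isopleth_area_km2 = iso$area_km2,
                                         settlement_area_km2 = settlement$area_km2))
  invisible(list(ud = ud, iso = iso, settlement = settlement, sigma2_m = s2))
}

read_settlement <- function(outdir, cfg) {
  ud_path <- file.path(outdir, "ud.asc")
  if (!file.exists(ud_path)) {
    stop("missing ", ud_path, "; run the ud stage first", call. = FALSE)
  }
  ud <- read_ud_raster(ud_path)
  main_component(isopleth(ud, 0.95), ud)
}

#' Movement-pattern segmentation stage
#'
#' Classifies every fix into the five movement patterns against the main
#' settlement polygon and writes `phases.csv`, `segments.json`, `nsd.csv`,
#' and `summary.json` (displacement metrics).
#'
#' @inheritParams run_ud
#' @return Invisibly, the `wolf_phases`.
#' @export
run_segment <- function(cfg, outdir) {
  traj <- load_traj(cfg, outdir)
  settlement <- read_settlement(outdir, cfg)
  rules <- seg_rules(cfg$segmentation$exploration_min_h,
                     cfg$segmentation$predispersal_min_days,
                     cfg$segmentation$post_release_min_days,
                     cfg$segmentation$buffer_m)
  phases <- classify_phases(traj, settlement, rules)
  utils::write.csv(data.frame(
    fix_id = seq_len(nrow(traj)),
    timestamp = format(traj$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    phase = phases$labels), file.path(outdir, "phases.csv"),
    row.names = FALSE, quote = FALSE)
  seg <- within(phases$segments, {
    start_time <- format(start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    end_time <- format(end_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  })
  writeLines(jsonlite::toJSON(seg, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), file.path(outdir, "segments.json"))
  utils::write.csv(data.frame(
    fix_id = seq_len(nrow(traj)), nsd_km2 = nsd_series(traj)),
    file.path(outdir, "nsd.csv"), row.names = FALSE, quote = FALSE)
  summ <- displacement_summary(traj, phases)
  writeLines(jsonlite::toJSON(summ[setdiff(names(summ), c("nsd_series",
    "min_daily_distance"))], auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(outdir, "summary.json"))
  write_manifest(outdir, "segment", cfg)
  invisible(phases)
}

read_phases <- function(outdir) {
  p <- file.path(outdir, "phases.csv")
  if (!file.exists(p)) stop("missing ", p, "; run the segment stage first",
                            call. = FALSE)
  df <- utils::read.csv(p, stringsAsFactors = FALSE)
  r <- rle(df$phase)
  end <- cumsum(r$lengths)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%SZ")
  structure(list(labels = df$phase,
                 segments = data.frame(phase = r$values,
                                       start_time = ts[end - r$lengths + 1L],
                                       end_time = ts[end],
                                       n_fixes = r$lengths),
                 inside = NULL), class = "wolf_phases")
}

#' Step statistics stage
#'
#' Computes steps with day/night labels and writes `steps.csv`, the
#' day-vs-night comparison per pattern (`table2.csv`) and the
#' between-pattern comparisons per period (`table3.csv`).
#'
#' @inheritParams run_ud
#' @return Invisibly, a list with `steps`, `table2`, `table3`.
#' @export
run_steps <- function(cfg, outdir) {
  traj <- load_traj(cfg, outdir)
  phases <- read_phases(outdir)
  steps <- compute_steps(traj)
  utils::write.csv(data.frame(
    t_from = format(steps$t_from, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    t_to = format(steps$t_to, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x_from = steps$x_from, y_from = steps$y_from,
    x_to = steps$x_to, y_to = steps$y_to,
    length_m = steps$length_m, duration_h = steps$duration_h,
    turning_angle_rad = steps$turning_angle_rad,
    period = steps$period, gap = steps$gap),
    file.path(outdir, "steps.csv"), row.names = FALSE, quote = FALSE)
  t2 <- run_table2(steps, phases, n_perm = cfg$stats$n_perm,
                   seed = cfg$seed + 2)
  t3 <- run_table3(steps, phases, n_perm = cfg$stats$n_perm,
                   seed = cfg$seed + 2)
  utils::write.csv(t2, file.path(outdir, "table2.csv"), row.names = FALSE)
  utils::write.csv(t3, file.path(outdir, "table3.csv"), row.names = FALSE)
  write_manifest(outdir, "steps", cfg)
  invisible(list(steps = steps, table2 = t2, table3 = t3))
}

#' Resting-site detection stage
#'
#' Detects resting sites on the regularised trajectory, annotates phase,
#' elevation and diurnality, and writes `resting_sites.csv` /
#' `resting_sites.geojson` plus the dispersal-plain subset used by the
#' selection stage.
#'
#' @inheritParams run_ud
#' @return Invisibly, the annotated `resting_sites`.
#' @export
run_rest <- function(cfg, outdir) {
  traj <- load_traj(cfg, outdir)
  phases <- read_phases(outdir)
  landscape <- read_landscape(file.path(outdir, "landscape"))
  sites <- detect_resting_sites(traj, radius = cfg$resting$radius,
                                min_hours = cfg$resting$min_hours,
                                merge_dist = cfg$resting$merge_dist,
                                phases = phases,
                                elevation = landscape$elevation)
  sites <- add_diurnality(sites, attr(traj, "crs"))
  utils::write.csv(as.data.frame(sites), file.path(outdir, "resting_sites.csv"),
                   row.names = FALSE)
  write_sites(sites, file.path(outdir, "resting_sites.geojson"))
  sel <- filter_dispersal_plain(sites, max_elev = cfg$resting$max_elev)
  utils::write.csv(as.data.frame(sel),
                   file.path(outdir, "resting_sites_dispersal_plain.csv"),
                   row.names = FALSE)
  write_manifest(outdir, "rest", cfg,
                 list(n_sites = nrow(sites), n_dispersal_plain = nrow(sel)))
  invisible(sites)
}

#' Resting-site selection stage
#'
#' Builds 1:25 matched choice sets for the dispersal-plain resting sites,
#' extracts covariates, selects buffer radii by preliminary univariate CLR,
#' filters correlated covariates, fits the full conditional logistic model,
#' and dredges with full model averaging. Writes `choice_sets.csv`,
#' `clr_fit.json`, `dredge_table.csv` and `averaged_model.json`.
#'
#' @inheritParams run_ud
#' @return Invisibly, a list with `fit`, `dredge`, `covariates`, `strata`.
#' @export
run_select <- function(cfg, outdir) {
  traj <- load_traj(cfg, outdir)
  sel_path <- file.path(outdir, "resting_sites_dispersal_plain.csv")
  if (!file.exists(sel_path)) {
    stop("missing ", sel_path, "; run the rest stage first", call. = FALSE)
  }
  sites <- utils::read.csv(sel_path, stringsAsFactors = FALSE)
  if (nrow(sites) < 2) {
    stop("fewer than 2 dispersal-plain resting sites; selection model not fitted",
         call. = FALSE)
  }
  sites$start_time <- as.POSIXct(sites$start_time, tz = "UTC")
  landscape <- read_landscape(file.path(outdir, "landscape"))
  cs <- build_choice_sets(sites, traj, landscape,
                          n_avail = cfg$selection$n_avail,
                          seed = cfg$seed + 1)
  covs <- lapply(cs, function(s) extract_covariates(
    s$xy, landscape,
    radii_density = cfg$selection$radii_density,
    radii_metrics = cfg$selection$radii_metrics,
    decay_scale = cfg$selection$decay_scale))
  strata <- lapply(covs, as.matrix)
  # choice_sets.csv: one row per location
  rows <- do.call(rbind, lapply(seq_along(cs), function(i) {
    cbind(data.frame(stratum = cs[[i]]$stratum_id,
                     role = c("used", rep("available", nrow(cs[[i]]$xy) - 1)),
                     x = cs[[i]]$xy[, 1], y = cs[[i]]$xy[, 2]), covs[[i]])
  }))
  utils::write.csv(rows, file.path(outdir, "choice_sets.csv"), row.names = FALSE)
  # preliminary radius selection per covariate family; a family whose
  # univariate fits all fail (no usable variation in these choice sets) is
  # dropped from the candidate set with a log entry
  fam_cols <- unlist(lapply(
    c("tree_density", "settlement_density", "patch_density"),
    function(fam) tryCatch(select_radius(strata, fam)$column,
                           error = function(e) {
                             wm_log("select: dropping covariate family ", fam,
                                    " (", conditionMessage(e), ")",
                                    level = "WARN")
                             NULL
                           })))
  cand <- c(fam_cols, "decay_dist_motorway", "decay_dist_primary",
            "decay_dist_river", "decay_dist_built", "decay_dist_tree")
  pooled <- do.call(rbind, strata)[, cand, drop = FALSE]
  retained <- correlation_filter(pooled, threshold = cfg$selection$cor_threshold)
  fit <- fit_clr(strata, covariates = retained)
  dr <- dredge_average(strata, retained, delta_aic = cfg$selection$delta_aic)
  writeLines(jsonlite::toJSON(list(
    covariates = retained, beta = as.list(fit$beta), se = as.list(fit$se),
    ci90_lo = as.list(fit$ci90[, "lo"]), ci90_hi = as.list(fit$ci90[, "hi"]),
    p_value = as.list(fit$p_value), loglik = fit$loglik, aic = fit$aic,
    n_strata = fit$n_strata, converged = fit$converged,
    standardized = fit$standardized),
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(outdir, "clr_fit.json"))
  utils::write.csv(dr$table, file.path(outdir, "dredge_table.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(list(
    full_average_beta = as.list(dr$full_average_beta),
    relative_importance = as.list(dr$relative_importance),
    retained_models = dr$retained),
    auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(outdir, "averaged_model.json"))
  write_manifest(outdir, "select", cfg, list(n_strata = fit$n_strata))
  invisible(list(fit = fit, dredge = dr, covariates = retained,
                 strata = strata, choice_sets = cs))
}

#' Run the full pipeline
#'
#' Chains simulate, ud, segment, steps, rest and select on a configuration.
#' When `simulate = FALSE` the run directory must already contain
#' `track.csv` and `landscape/`.
#'
#' @param cfg A `run_config` (or path to a YAML file).
#' @param outdir Run directory.
#' @param simulate Generate the synthetic dataset first (default `TRUE`).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_all <- function(cfg, outdir, simulate = TRUE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (simulate) run_simulate(cfg, outdir) else NULL
  ud <- run_ud(cfg, outdir)
  phases <- run_segment(cfg, outdir)
  steps <- run_steps(cfg, outdir)
  rest <- run_rest(cfg, outdir)
  sel <- tryCatch(run_select(cfg, outdir), error = function(e) {
    wm_log("select stage skipped: ", conditionMessage(e), level = "WARN")
    NULL
  })
  invisible(list(sim = sim, ud = ud, phases = phases, steps = steps,
                 rest = rest, select = sel))
}
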