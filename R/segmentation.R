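# Rule-based classification of fixes into the five movement patterns:
# post_release, settlement, exploration, pre_dispersal, dispersal.
#
# The patterns are defined relative to the 95% UD polygon (the settlement
# area): outside-runs of >= 12 h and < 6 days that return inside are
# exploration; returning outside-runs of more than 6 days are pre-dispersal;
# a terminal outside-run that never returns is dispersal; the initial span
# until the first sustained inside-occupancy is post-release; everything
# else (including sub-12 h sorties) is settlement. These run-length rules
# make the published visual-inspection criteria deterministic.

#' Segmentation rules
#'
#' @param exploration_min_h Minimum outside-run span for exploration (h).
#' @param predispersal_min_days Outside-run span (days) beyond which a
#'   returning run is pre-dispersal rather than exploration.
#' @param post_release_min_days Sustained inside-occupancy (days) that ends
#'   the post-release phase.
#' @param buffer_m Tolerance (m) around the settlement polygon when testing
#'   fix containment.
#' @return A list of class `seg_rules`.
#' @export
seg_rules <- function(exploration_min_h = 12, predispersal_min_days = 6,
                      post_release_min_days = 2, buffer_m = 0) {
  structure(list(exploration_min_h = exploration_min_h,
                 predispersal_min_days = predispersal_min_days,
                 post_release_min_days = post_release_min_days,
                 buffer_m = buffer_m),
            class = "seg_rules")
}

PHASES <- c("post_release", "settlement", "exploration", "pre_dispersal",
            "dispersal")

#' Classify fixes into the five movement patterns
#'
#' Single-pass rule application against the supplied settlement polygon. For
#' animals that disperse immediately after release and only later settle (so
#' that the full-track UD polygon sits away from the release site), a second
#' pass relabels the initial transit to the eventual settlement area as
#' dispersal (`two_pass = TRUE`, the default); the pass count is logged.
#'
#' @param traj A `wolf_traj`.
#' @param settlement An `wm_isopleth` (95% UD region) in the same CRS.
#' @param rules A [seg_rules()] object.
#' @param two_pass Allow relabelling of an immediate post-release dispersal.
#' @return A `wolf_phases`: list with `labels` (character per fix),
#'   `segments` (data.frame phase/start/end/n_fixes), `inside` (logical per
#'   fix).
#' @export
classify_phases <- function(traj, settlement, rules = seg_rules(),
                            two_pass = TRUE) {
  n <- nrow(traj)
  stopifnot(n >= 1)
  t <- as.numeric(traj$timestamp)
  inside <- isopleth_contains(settlement, traj$x, traj$y, rules$buffer_m)
  if (!any(inside)) {
    wm_log("classify_phases: trajectory entirely outside settlement polygon; ",
           "labelling all fixes dispersal (degenerate)", level = "WARN")
    labels <- rep("dispersal", n)
    return(build_phases(traj, labels, inside))
  }
  labels <- rep(NA_character_, n)

  # (5) post-release: release until first entry into sustained occupancy
  occ_start <- sustained_occupancy_start(inside, t,
                                         rules$post_release_min_days * 86400)
  if (is.na(occ_start)) occ_start <- which(inside)[1]  # no sustained run: first entry
  if (occ_start > 1) labels[seq_len(occ_start - 1)] <- "post_release"

  # (2)-(4) outside-runs after the post-release span
  idx <- occ_start:n
  runs <- logical_runs(!inside[idx])
  for (k in seq_len(nrow(runs))) {
    if (!runs$value[k]) next
    i0 <- idx[runs$start[k]]
    i1 <- idx[runs$end[k]]
    span_s <- t[i1] - t[i0]
    terminal <- i1 == n
    lab <- if (terminal) {
      "dispersal"
    } else if (span_s >= rules$predispersal_min_days * 86400) {
      "pre_dispersal"
    } else if (span_s >= rules$exploration_min_h * 3600) {
      "exploration"
    } else {
      "settlement"  # absorbed short sortie
    }
    labels[i0:i1] <- lab
  }
  labels[is.na(labels)] <- "settlement"

  passes <- 1L
  if (two_pass && occ_start > 1) {
    # Immediate disperser: the pre-settlement span is a directional transit to
    # the eventual settlement area, not ordinary post-release wandering, when
    # it lasts longer than the post-release rule alone explains and ends far
    # from the release site.
    pre <- seq_len(occ_start - 1)
    span_s <- t[occ_start] - t[1]
    d_release <- sqrt((traj$x[occ_start] - traj$x[1])^2 +
                      (traj$y[occ_start] - traj$y[1])^2)
    if (span_s > rules$predispersal_min_days * 86400 && d_release > 0 &&
        !isopleth_contains(settlement, traj$x[1], traj$y[1], rules$buffer_m)) {
      passes <- 2L
      # keep an initial non-directional post-release stub: fixes before the
      # animal first moves beyond twice the polygon buffer... use NSD takeoff:
      nsd <- (traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2
      take <- which(nsd[pre] > (stats::quantile(sqrt(nsd[pre]), 0.1) * 3 + 1e3)^2)[1]
      if (is.na(take)) take <- 1L
      if (take > 1) labels[seq_len(take - 1)] <- "post_release"
      labels[take:(occ_start - 1)] <- "dispersal"
    }
  }
  wm_log(sprintf("classify_phases: %d pass(es)", passes))
  build_phases(traj, labels, inside)
}

# First index at which an inside-run of duration >= min_s begins; NA if none.
sustained_occupancy_start <- function(inside, t, min_s) {
  runs <- logical_runs(inside)
  for (k in seq_len(nrow(runs))) {
    if (!runs$value[k]) next
    if (t[runs$end[k]] - t[runs$start[k]] >= min_s) return(runs$start[k])
  }
  NA_integer_
}

logical_runs <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  data.frame(value = r$values, start = end - r$lengths + 1L, end = end)
}

build_phases <- function(traj, labels, inside) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  segments <- data.frame(
    phase = r$values,
    start_time = traj$timestamp[start],
    end_time = traj$timestamp[end],
    n_fixes = r$lengths
  )
  structure(list(labels = labels, segments = segments, inside = inside),
            class = "wolf_phases")
}

#' @export
print.wolf_phases <- function(x, ...) {
  cat("<wolf_phases>\n")
  print(x$segments)
  invisible(x)
}
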