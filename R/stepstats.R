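# Permutation Mann-Whitney comparisons of step lengths (day vs night within
# movement patterns, and between patterns within period), and pairwise
# Wilcoxon tests of resting-site diurnality between individuals.
#
# Step-length distributions are strongly right-skewed, so all comparisons
# are rank-based. The U statistic is reported in its normalised
# common-language form U/(n1*n2) in [0, 1]: the probability that a value
# from the second sample exceeds one from the first (ties counted half).

#' Permutation Mann-Whitney test
#'
#' Computes U with midrank tie handling and a two-sided permutation p-value
#' over label relabellings: `p = (1 + #{ |U' - E[U]| >= |U - E[U]| }) /
#' (n_perm + 1)`. When the number of distinct label assignments
#' `choose(n1 + n2, n2)` does not exceed `n_perm` the full assignment set is
#' enumerated instead and the p-value is exact (the observed assignment
#' counts itself, so the estimator is the same up to the +1 guard).
#'
#' @param a,b Numeric samples.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed making the permutation draw reproducible;
#'   `NULL` uses the current RNG state.
#' @return A list of class `rank_test`: `u_norm` = P(b > a), `p_value`,
#'   `n1`, `n2`, `n_perm` (permutations actually used), `exact`, `seed`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
mann_whitney_perm <- function(a, b, n_perm = 10000, seed = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1, n_perm >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both samples; test is degenerate")
    return(structure(list(u_norm = 0.5, p_value = 1, n1 = n1, n2 = n2,
                          n_perm = n_perm, seed = seed,
                          mean_a = mean(a), sd_a = stats::sd(a),
                          mean_b = mean(b), sd_b = stats::sd(b)),
                     class = "rank_test"))
  }
  # U for sample b over a: rank-sum of b minus its minimum
  U <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2
  EU <- n1 * n2 / 2
  obs <- abs(U - EU)
  n <- n1 + n2
  n_assign <- choose(n, n2)
  exact <- is.finite(n_assign) && n_assign <= n_perm
  if (exact) {
    sel <- utils::combn(n, n2)
    Uperm <- colSums(matrix(r[sel], nrow = n2)) - n2 * (n2 + 1) / 2
    p <- sum(abs(Uperm - EU) >= obs - 1e-9) / ncol(sel)
    n_used <- ncol(sel)
  } else {
    perm_idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n2),
                       integer(n2))
    Uperm <- colSums(matrix(r[perm_idx], nrow = n2)) - n2 * (n2 + 1) / 2
    p <- (1 + sum(abs(Uperm - EU) >= obs - 1e-9)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(u_norm = U / (n1 * n2), p_value = p, n1 = n1, n2 = n2,
                 n_perm = n_used, exact = exact, seed = seed,
                 mean_a = mean(a), sd_a = stats::sd(a),
                 mean_b = mean(b), sd_b = stats::sd(b)),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (permutation): U = %.3f, p = %.4g (n1 = %d, n2 = %d, %d perms)\n",
              x$u_norm, x$p_value, x$n1, x$n2, x$n_perm))
  invisible(x)
}

# Pool pre-dispersal and dispersal into "dispersal" for the step-length
# tables; twilight steps are excluded throughout.
pool_phase <- function(phase) {
  ifelse(phase == "pre_dispersal", "dispersal", phase)
}

# Steps with the phase of their end fix attached (the fix the step leads to),
# twilight excluded.
steps_with_phase <- function(steps, phases) {
  lab <- phases$labels
  # steps row i goes from fix i to fix i+1
  phase <- pool_phase(lab[-1])
  df <- cbind(steps, phase = phase)
  df[df$period != "twilight", , drop = FALSE]
}

#' Day versus night step lengths within each movement pattern
#'
#' One permutation Mann-Whitney test per pattern (pre-dispersal pooled with
#' dispersal), with `u_norm` oriented as P(night step > day step).
#'
#' @param steps A `wolf_steps` with `period` labels.
#' @param phases A `wolf_phases` for the same trajectory.
#' @param n_perm,seed Passed to [mann_whitney_perm()]; the seed is advanced
#'   per phase so tests are independent but reproducible.
#' @return Data.frame with one row per pattern present: group sizes, day and
#'   night mean +/- SD (m), `u_norm`, `p_value`, and a `sufficient` flag
#'   (FALSE when either period has fewer than 2 steps).
#' @export
run_table2 <- function(steps, phases, n_perm = 10000, seed = 1) {
  df <- steps_with_phase(steps, phases)
  out <- list()
  phase_order <- c("post_release", "settlement", "exploration", "dispersal")
  # phases come from the labelling, so a pattern whose steps are all
  # twilight still appears (flagged insufficient) rather than vanishing
  present <- intersect(phase_order, unique(pool_phase(phases$labels)))
  for (ph in present) {
    day <- df$length_m[df$phase == ph & df$period == "day"]
    night <- df$length_m[df$phase == ph & df$period == "night"]
    row <- data.frame(phase = ph, n_day = length(day), n_night = length(night),
                      day_mean = if (length(day)) mean(day) else NA_real_,
                      day_sd = if (length(day) > 1) stats::sd(day) else NA_real_,
                      night_mean = if (length(night)) mean(night) else NA_real_,
                      night_sd = if (length(night) > 1) stats::sd(night) else NA_real_,
                      u_norm = NA_real_, p_value = NA_real_,
                      sufficient = length(day) >= 2 && length(night) >= 2)
    if (row$sufficient) {
      tst <- mann_whitney_perm(day, night, n_perm = n_perm,
                               seed = seed + match(ph, phase_order))
      row$u_norm <- tst$u_norm
      row$p_value <- tst$p_value
    }
    out[[ph]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Step lengths between movement patterns, separately by period
#'
#' All pairwise pattern comparisons of step length within day steps and
#' within night steps; `u_norm` is oriented as P(second-listed pattern >
#' first-listed pattern).
#'
#' @inheritParams run_table2
#' @return Data.frame with one row per (period, pattern pair) present.
#' @export
run_table3 <- function(steps, phases, n_perm = 10000, seed = 1) {
  df <- steps_with_phase(steps, phases)
  phase_order <- c("post_release", "settlement", "exploration", "dispersal")
  present <- intersect(phase_order, unique(pool_phase(phases$labels)))
  out <- list()
  k <- 0L
  for (per in c("day", "night")) {
    if (length(present) < 2) next
    for (i in seq_len(length(present) - 1)) for (j in (i + 1):length(present)) {
      k <- k + 1L
      g1 <- df$length_m[df$phase == present[i] & df$period == per]
      g2 <- df$length_m[df$phase == present[j] & df$period == per]
      row <- data.frame(period = per, phase_a = present[i], phase_b = present[j],
                        n_a = length(g1), n_b = length(g2),
                        u_norm = NA_real_, p_value = NA_real_,
                        sufficient = length(g1) >= 2 && length(g2) >= 2)
      if (row$sufficient) {
        tst <- mann_whitney_perm(g1, g2, n_perm = n_perm, seed = seed + 100 + k)
        row$u_norm <- tst$u_norm
        row$p_value <- tst$p_value
      }
      out[[k]] <- row
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pairwise Wilcoxon rank-sum tests of diurnality between individuals
#'
#' Unpaired exact/normal-approximation rank-sum test per unordered pair of
#' individuals, with Holm-adjusted p-values alongside the raw ones.
#'
#' @param groups Named list: individual id -> numeric vector of resting-site
#'   diurnality values in \[0, 1\].
#' @return Data.frame with `group_a`, `group_b`, `n1`, `n2`, `u_norm`,
#'   `p_raw`, `p_holm`.
#' @export
pairwise_wilcoxon <- function(groups) {
  stopifnot(length(groups) >= 2)
  ids <- names(groups)
  out <- list()
  k <- 0L
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    a <- groups[[i]]; b <- groups[[j]]
    if (!length(a) || !length(b)) {
      warning(sprintf("skipping pair %s-%s: empty group", ids[i], ids[j]))
      next
    }
    k <- k + 1L
    wt <- suppressWarnings(stats::wilcox.test(b, a, exact = NULL))
    r <- rank(c(a, b))
    U <- sum(r[(length(a) + 1):(length(a) + length(b))]) -
      length(b) * (length(b) + 1) / 2
    out[[k]] <- data.frame(group_a = ids[i], group_b = ids[j],
                           n1 = length(a), n2 = length(b),
                           u_norm = U / (length(a) * length(b)),
                           p_raw = wt$p.value)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$p_holm <- stats::p.adjust(res$p_raw, method = "holm")
  res
}
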