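#' Omega-squared explained variance for grouped observations
#'
#' The bias-adjusted fraction of variance in `x` explained by the grouping:
#' `(SSB - df * MSE) / (SST + MSE)` with `df = G - 1` and MSE the
#' within-group mean square (within-group sum of squares over `N - G`).
#' The raw value is returned and may be negative; degenerate inputs with
#' zero total variance return 0.  A `"printed"` MSE mode using the raw
#' within-group sum of squares is kept for comparison, but it is not a
#' variance fraction and is never used by the pipeline.
#'
#' @param x Numeric observations (e.g. per-trial rates in one time bin).
#' @param g Grouping vector (3 task conditions; other counts are allowed
#'   with a warning).
#' @param mse_mode "standard" (default) or "printed".
#' @return Numeric omega-squared.
#' @export
omega_squared <- function(x, g, mse_mode = c("standard", "printed")) {
  mse_mode <- match.arg(mse_mode)
  g <- as.factor(g)
  stopifnot(length(x) == length(g))
  if (nlevels(g) != 3) {
    warning(sprintf("omega_squared: %d groups (task variables have 3)",
                    nlevels(g)))
  }
  if (any(tabulate(g, nbins = nlevels(g)) == 0)) {
    stop("omega_squared: empty group")
  }
  N <- length(x)
  G <- nlevels(g)
  gm <- mean(x)
  mi <- tapply(x, g, mean)
  ni <- tabulate(g)
  ssb <- sum(ni * (mi - gm)^2)
  sst <- sum((x - gm)^2)
  ssw <- sst - ssb
  mse <- if (mse_mode == "standard") ssw / (N - G) else ssw
  den <- sst + mse
  if (den <= 0) return(0)
  (ssb - (G - 1) * mse) / den
}

# vectorized omega-squared across the columns of a trials x bins matrix
omega_squared_cols <- function(X, g) {
  g <- as.factor(g)
  N <- nrow(X)
  G <- nlevels(g)
  ni <- tabulate(g)
  ind <- stats::model.matrix(~ g - 1)
  gs <- crossprod(ind, X)            # G x bins group sums
  gm <- colMeans(X)
  mi <- gs / ni
  ssb <- colSums(ni * sweep(mi, 2, gm)^2)
  sst <- colSums(sweep(X, 2, gm)^2)
  ssw <- pmax(sst - ssb, 0)
  mse <- ssw / (N - G)
  den <- sst + mse
  out <- (ssb - (G - 1) * mse) / den
  out[den <= 0] <- 0
  out
}

#' Omega-squared time course with balanced trial subsampling
#'
#' For each unit and time bin, conditions are balanced by randomly
#' subsampling every condition (without replacement) down to the smallest
#' condition count; omega-squared is averaged over `reps` such draws.  One
#' draw of trials per repetition is reused across all bins.
#'
#' @param tensor A [bin_spikes()] rate tensor (150 ms bins stepped by
#'   15 ms for the selectivity analyses).
#' @param labels Condition label per trial (aligned with the tensor's
#'   trial axis).
#' @param reps Number of balanced draws (50 in the full analysis).
#' @param seed RNG seed.
#' @return List of class `omega_series`: `omega` (units x bins matrix),
#'   `centers_s`, `reps`, and the per-unit usable-trial mask.
#' @export
omega_timecourse <- function(tensor, labels, reps = 50, seed = 1L) {
  counts <- tensor$counts
  nu <- dim(counts)[1]
  nb <- dim(counts)[3]
  labels <- as.factor(labels)
  stopifnot(length(labels) == dim(counts)[2])
  min_n <- min(tabulate(labels, nbins = nlevels(labels)))
  if (min_n < 2) stop("fewer than 2 trials in some condition")
  idx_by_cond <- split(seq_along(labels), labels)
  omega <- matrix(0, nu, nb)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      take <- unlist(lapply(idx_by_cond, function(ix) {
        if (length(ix) == min_n) ix else sample(ix, min_n)
      }))
      g <- labels[take]
      # all (unit, bin) columns at once; bins invalid on any selected
      # trial propagate NA
      X <- matrix(aperm(counts[, take, , drop = FALSE], c(2, 1, 3)),
                  nrow = length(take))
      omega <- omega + matrix(omega_squared_cols(X, g), nu, nb) / reps
    }
  })
  structure(list(omega = omega, centers_s = tensor$centers_s, reps = reps,
                 unit_ids = tensor$unit_ids),
            class = "omega_series")
}

#' Onset latency of selectivity
#'
#' First time bin, at or after the IS onset, whose statistic exceeds the
#' pointwise `level` percentile of the null distribution.  Works on a
#' population-mean series or per unit.
#'
#' @param observed Numeric series (bins), e.g. population mean omega.
#' @param centers_s Bin centers (s, relative to IS onset).
#' @param null_stack Iterations x bins null matrix (same statistic).
#' @param level Pointwise percentile (99.9 in the full analysis).
#' @param from Time from which onsets count (default 0 = IS onset).
#' @return Latency in seconds (bin center), or `NA` if never significant.
#' @export
onset_latency <- function(observed, centers_s, null_stack, level = 99.9,
                          from = 0) {
  thr <- apply(null_stack, 2, quantile, probs = level / 100, names = FALSE)
  sig <- observed > thr & centers_s >= from
  if (!any(sig, na.rm = TRUE)) return(NA_real_)
  centers_s[which(sig)[1]]
}

#' Epoch-wise selective cells and percentages
#'
#' Recomputes balanced omega-squared in single epoch-wide bins (early
#' 50-450 ms and late 500-900 ms of the IS period by default) and flags
#' units whose observed value exceeds the `1 - alpha` quantile of a
#' within-unit label-shuffle null.
#'
#' @param session A [pf_session()].
#' @param variable Trial condition column.
#' @param units Units to test (default all).
#' @param epochs Named list of IS-relative windows (s).
#' @param n_shuffle Label shuffles per unit.
#' @param alpha Significance level.
#' @param reps Balanced draws per omega estimate.
#' @param seed RNG seed.
#' @return List with `flags` (unit x epoch logical), `omega` (observed),
#'   and `percentages` per epoch.
#' @export
epoch_selective_cells <- function(session, variable, units = NULL,
                                  epochs = list(early = c(0.05, 0.45),
                                                late = c(0.50, 0.90)),
                                  n_shuffle = 1000, alpha = 0.05,
                                  reps = 50, seed = 1L) {
  tr <- session$trials
  keep_tr <- tr$correct & !tr$correction & !is.na(tr[[variable]])
  flags <- NULL
  omegas <- NULL
  for (ep in names(epochs)) {
    w <- epochs[[ep]]
    tens <- bin_spikes(session, align = "is", window = w,
                       width_ms = 1000 * (w[2] - w[1]),
                       step_ms = 1000 * (w[2] - w[1]), units = units)
    counts <- tens$counts[, keep_tr, 1, drop = FALSE]
    labels <- as.factor(tr[[variable]][keep_tr])
    nu <- dim(counts)[1]
    obs <- numeric(nu)
    pval <- numeric(nu)
    with_seed(stream_seed(seed, paste0("epoch-", ep)), {
      for (u in seq_len(nu)) {
        x <- counts[u, , 1]
        obs[u] <- balanced_omega_once(x, labels, reps)
        null <- vapply(seq_len(n_shuffle), function(i) {
          balanced_omega_once(x, sample(labels), 1)
        }, numeric(1))
        pval[u] <- (sum(null >= obs[u]) + 1) / (n_shuffle + 1)
      }
    })
    flags <- cbind(flags, pval < alpha)
    omegas <- cbind(omegas, obs)
  }
  colnames(flags) <- colnames(omegas) <- names(epochs)
  rownames(flags) <- rownames(omegas) <- tens$unit_ids
  list(flags = flags, omega = omegas,
       percentages = 100 * colMeans(flags))
}

# mean balanced omega-squared of one value vector over `reps` draws
balanced_omega_once <- function(x, labels, reps) {
  idx_by_cond <- split(seq_along(labels), labels)
  min_n <- min(lengths(idx_by_cond))
  mean(vapply(seq_len(reps), function(r) {
    take <- unlist(lapply(idx_by_cond, function(ix) {
      if (length(ix) == min_n) ix else sample(ix, min_n)
    }))
    omega_squared(x[take], labels[take])
  }, numeric(1)))
}

#' Match a population's mean firing rate by removing high-rate units
#'
#' Units are sorted by rate and the highest-rate unit removed iteratively
#' until the population mean is at most `target_mean + tol`.
#'
#' @param rates Named numeric vector of unit firing rates.
#' @param target_mean Target mean rate (sp/s).
#' @param tol Tolerance band.
#' @return List with `units` (retained names), `n_removed`, `mean_rate`.
#' @export
rate_match_population <- function(rates, target_mean = 2.5, tol = 0.2) {
  stopifnot(!is.null(names(rates)))
  removed <- 0L
  r <- rates
  while (mean(r) > target_mean + tol) {
    if (length(r) <= 1) {
      stop(sprintf(
        "cannot reach target mean %.2f: closest achievable is %.2f",
        target_mean, mean(r)))
    }
    r <- r[-which.max(r)]
    removed <- removed + 1L
  }
  list(units = names(r), n_removed = removed, mean_rate = mean(r))
}

#' Task-related unit filter
#'
#' A unit is task-related if its per-trial firing rate in the baseline
#' (fixation 0-1 s) differs significantly (Kruskal-Wallis, p < alpha)
#' from the early (50-400 ms) or the late (400-900 ms) IS phase.  Also
#' flags units whose session-wide rate is at or below `low_rate_hz`.
#'
#' @param session A [pf_session()].
#' @param alpha Significance level.
#' @param early,late IS-relative windows (s).
#' @param baseline Fixation-relative window (s).
#' @param low_rate_hz Low-rate exclusion threshold.
#' @return Data frame with unit_id, task_related, p_early, p_late,
#'   low_rate.
#' @export
task_related_filter <- function(session, alpha = 0.05,
                                early = c(0.05, 0.40),
                                late = c(0.40, 0.90),
                                baseline = c(0, 1),
                                low_rate_hz = 0.5) {
  base <- bin_spikes(session, align = "fixation", window = baseline,
                     width_ms = 1000 * diff(baseline),
                     step_ms = 1000 * diff(baseline))
  e <- bin_spikes(session, align = "is", window = early,
                  width_ms = 1000 * diff(early),
                  step_ms = 1000 * diff(early))
  l <- bin_spikes(session, align = "is", window = late,
                  width_ms = 1000 * diff(late),
                  step_ms = 1000 * diff(late))
  tr <- session$trials
  total_time <- sum(tr$go_s + 1 - tr$fixation_onset_s)
  sp_n <- table(factor(session$spikes$unit_id,
                       levels = session$units$unit_id))
  rows <- lapply(seq_along(session$units$unit_id), function(ui) {
    u <- session$units$unit_id[ui]
    rb <- base$rates[ui, , 1]
    re <- e$rates[ui, , 1]
    rl <- l$rates[ui, , 1]
    kw <- function(a, b) {
      a <- a[!is.na(a)]
      b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2 ||
          (sd(c(a, b)) == 0)) return(1)
      kruskal.test(list(a, b))$p.value
    }
    p_e <- kw(rb, re)
    p_l <- kw(rb, rl)
    data.frame(unit_id = u,
               task_related = (p_e < alpha) | (p_l < alpha),
               p_early = p_e, p_late = p_l,
               low_rate = (sp_n[[u]] / total_time) <= low_rate_hz,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
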