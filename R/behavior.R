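#' Moving-average performance curve
#'
#' For each trial `k` with a fully contained window of `2w + 1` trials,
#' the proportion correct `p_k` is the mean of the binary correctness
#' indicators over trials `k - w` to `k + w`.  Edge trials without a full
#' window are undefined (no partial windows).
#'
#' @param n Binary (0/1 or logical) correctness sequence, 1-based trials.
#' @param w Half-window in trials (window length `2w + 1`).
#' @return Data frame with columns `k` and `p_k`.
#' @export
moving_average_performance <- function(n, w = 2) {
  n <- as.integer(n)
  stopifnot(all(n %in% c(0L, 1L)), w >= 1)
  len <- length(n)
  if (len < 2 * w + 1) stop("sequence shorter than the moving window")
  ks <- (w + 1):(len - w)
  cs <- cumsum(n)
  sums <- cs[ks + w] - c(0, cs)[ks - w]
  data.frame(k = ks, p_k = sums / (2 * w + 1))
}

#' Minimum correct count for a significant window
#'
#' Smallest `m` such that `P(Binomial(window_len, p_null) >= m) < alpha`;
#' `NA` when even a fully correct window is not significant.
#'
#' @param window_len Window length in trials.
#' @param p_null Probability correct under the null.
#' @param alpha Significance level.
#' @return Integer count, or `NA_integer_` if unattainable.
#' @export
min_successes <- function(window_len, p_null, alpha = 0.05) {
  stopifnot(p_null > 0, p_null < 1, alpha > 0, alpha < 1, window_len >= 1)
  # P(X >= m) = pbinom(m - 1, n, p, lower.tail = FALSE)
  tail <- pbinom(seq_len(window_len) - 1, window_len, p_null,
                 lower.tail = FALSE)
  ok <- which(tail < alpha)
  if (!length(ok)) return(NA_integer_)
  as.integer(ok[1])
}

#' Estimate the learning-completion trial
#'
#' The learning trial is the center of the earliest fully contained
#' `2w + 1` window whose correct count reaches [min_successes()] (with
#' `w = 2` and `p_null = 0.45` this requires all 5 trials correct).
#'
#' @param n Binary correctness sequence.
#' @param w Half-window.
#' @param p_null Null probability correct.
#' @param alpha Significance level.
#' @param min_trials Optional guard: error if fewer trials were recorded
#'   (session-selection rule uses 42).
#' @return The learning trial `k` (1-based), or `NA_integer_` ("not
#'   learned").
#' @export
estimate_learning_trial <- function(n, w = 2, p_null = 0.45, alpha = 0.05,
                                    min_trials = NULL) {
  if (!is.null(min_trials) && length(n) < min_trials) {
    stop(sprintf("session has %d trials; %d required", length(n),
                 min_trials))
  }
  m <- min_successes(2 * w + 1, p_null, alpha)
  if (is.na(m)) return(NA_integer_)
  perf <- moving_average_performance(n, w)
  hit <- which(perf$p_k * (2 * w + 1) >= m - 1e-9)
  if (!length(hit)) return(NA_integer_)
  as.integer(perf$k[hit[1]])
}

#' Split a session into learning and post-learning blocks
#'
#' The learning block runs from the first trial to the learning-completion
#' trial `k` inclusive; the post-learning block from `k + 1` to the last
#' trial.  The partition is exact and disjoint.
#'
#' @param session A [pf_session()].
#' @param k Learning-completion trial (1-based trial id).
#' @return List with `learning` and `post_learning` trial-id vectors.
#' @export
split_blocks <- function(session, k) {
  if (is.na(k)) stop("cannot split blocks: learning trial undefined")
  ids <- session$trials$trial_id
  stopifnot(k %in% ids)
  learning <- ids[ids <= k]
  post <- ids[ids > k]
  if (!length(post)) {
    warning("post-learning block is empty (k is the last trial)")
  }
  list(learning = learning, post_learning = post)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Across-session performance curve over early trials
#'
#' Mean percentage of correct choices per trial index (2nd to
#' `first_trials`-th trial) across sessions, with a Wilson 95% confidence
#' interval on the pooled proportion.
#'
#' @param sessions List of at least two [pf_session()]s (or of their trial
#'   tables).
#' @param first_trials Last trial index included (curve covers indices
#'   `2:first_trials`).
#' @param conf Confidence level.
#' @return Data frame with trial, pct_correct, lower, upper, n_sessions.
#' @export
performance_curve <- function(sessions, first_trials = 50, conf = 0.95) {
  if (length(sessions) < 2) {
    stop("performance_curve needs at least two sessions")
  }
  tabs <- lapply(sessions, function(s) {
    if (inherits(s, "pf_session")) s$trials else s
  })
  idx <- 2:first_trials
  rows <- lapply(idx, function(t) {
    vals <- vapply(tabs, function(tr) {
      if (t <= nrow(tr)) as.numeric(tr$correct[tr$trial_id == t]) else
        NA_real_
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    ci <- wilson_ci(sum(vals), length(vals), conf)
    data.frame(trial = t, pct_correct = 100 * mean(vals),
               lower = 100 * ci[["lower"]], upper = 100 * ci[["upper"]],
               n_sessions = length(vals))
  })
  do.call(rbind, rows)
}
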