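#' Recompute a mean waveform after rejecting outlier spikes
#'
#' Any spike waveform exceeding 3 standard deviations from the initial
#' average at ANY sample point is rejected and the mean recomputed.
#'
#' @param spike_waveforms Numeric matrix, spikes x samples.
#' @param n_sd Rejection threshold in SDs.
#' @return List with `mean`, `sd` (per-sample), `n_rejected`,
#'   `fraction_rejected`.
#' @export
clean_waveform <- function(spike_waveforms, n_sd = 3) {
  stopifnot(is.matrix(spike_waveforms), nrow(spike_waveforms) >= 2)
  m0 <- colMeans(spike_waveforms)
  s0 <- apply(spike_waveforms, 2, sd)
  s0[s0 == 0] <- .Machine$double.eps
  dev <- abs(sweep(sweep(spike_waveforms, 2, m0), 2, s0, "/"))
  reject <- apply(dev, 1, max) > n_sd
  if (all(reject)) stop("all spike waveforms rejected by the 3 SD rule")
  kept <- spike_waveforms[!reject, , drop = FALSE]
  list(mean = colMeans(kept),
       sd = apply(kept, 2, sd),
       n_rejected = sum(reject),
       fraction_rejected = mean(reject))
}

# locate main trough (global minimum) and the surrounding positive peaks
waveform_extrema <- function(v) {
  trough <- which.min(v)
  post <- if (trough < length(v)) {
    trough + which.max(v[(trough + 1):length(v)])
  } else NA_integer_
  pre <- if (trough > 1) which.max(v[1:(trough - 1)]) else NA_integer_
  list(trough = trough, post_peak = post, pre_peak = pre)
}

#' Amplitude quality-control rules for a mean waveform
#'
#' Drops axon-like waveforms: those whose main trough amplitude is smaller
#' than the following peak, or whose preceding peak is more than 20%
#' greater than the main trough.
#'
#' @param v Numeric mean waveform (raw or interpolated samples).
#' @return List with `keep` (logical) and `reason` (character).
#' @export
qc_exclude <- function(v) {
  ex <- waveform_extrema(v)
  trough_amp <- abs(v[ex$trough])
  if (is.na(ex$post_peak)) {
    return(list(keep = FALSE, reason = "no peak"))
  }
  post_amp <- abs(v[ex$post_peak])
  if (trough_amp < post_amp) {
    return(list(keep = FALSE, reason = "trough smaller than next peak"))
  }
  if (!is.na(ex$pre_peak)) {
    pre_amp <- abs(v[ex$pre_peak])
    if (v[ex$pre_peak] > 0 && pre_amp > 1.2 * trough_amp) {
      return(list(keep = FALSE, reason = "pre-peak 20% greater than trough"))
    }
  }
  list(keep = TRUE, reason = "ok")
}

#' Cubic interpolation of a waveform
#'
#' Upsamples a mean waveform by `factor` (default 10: 25 us to 2.5 us)
#' using a cubic spline through the raw samples.
#'
#' @param v Numeric raw waveform.
#' @param factor Integer upsampling factor.
#' @return Numeric vector of length `(length(v) - 1) * factor + 1`.
#' @export
interpolate_waveform <- function(v, factor = 10) {
  n <- length(v)
  spline(seq_len(n), v, xout = seq(1, n, by = 1 / factor),
         method = "fmm")$y
}

#' Trough-to-peak duration of a mean waveform
#'
#' The waveform is cubic-interpolated (25 us to 2.5 us), normalized so the
#' main trough is -1, and the duration measured as the distance from the
#' main trough to the following peak on the interpolated trace.
#'
#' @param v Numeric raw waveform samples.
#' @param sampling_interval_us Raw sampling interval (microseconds).
#' @param factor Interpolation factor.
#' @return List with `t2p_ms`, `trough_idx`, `peak_idx` (interpolated
#'   indices), `at_end` flag (peak at trace end: monotone tail) and the
#'   normalized `interpolated` trace.
#' @export
measure_trough_to_peak <- function(v, sampling_interval_us = 25,
                                   factor = 10) {
  vi <- interpolate_waveform(v, factor)
  vi <- vi / abs(min(vi)) # normalize: trough = -1
  ex <- waveform_extrema(vi)
  if (is.na(ex$post_peak)) stop("no post-trough samples to measure")
  dt_ms <- sampling_interval_us / factor / 1000
  list(t2p_ms = (ex$post_peak - ex$trough) * dt_ms,
       trough_idx = ex$trough, peak_idx = ex$post_peak,
       at_end = ex$post_peak == length(vi),
       interpolated = vi)
}

#' Hartigan dip statistic
#'
#' Minimal sup-norm distance between the empirical distribution function
#' and the nearest unimodal distribution function, computed from the
#' definition via greatest-convex-minorant / least-concave-majorant
#' deviations over all candidate modes (midpoint ECDF convention).
#'
#' @param x Numeric sample.
#' @return The dip statistic (0 for constant input).
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) <= 1) return(0)
  dip_stat_cpp(as.numeric(x))
}

#' Test the bimodality of a distribution with the dip statistic
#'
#' Reports the dip statistic with two Monte-Carlo p-values: the original
#' test against a uniform null, and a calibrated variant against a
#' moment-matched Gaussian null, which is more sensitive for
#' near-Gaussian unimodal alternatives.
#'
#' @param x Numeric sample (n >= 10).
#' @param n_mc Monte-Carlo iterations per null.
#' @param seed RNG seed.
#' @return List with `dip`, `p_original`, `p_calibrated`, `n`.
#' @export
test_bimodality <- function(x, n_mc = 10000, seed = 1L) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 10)
  d <- dip_statistic(x)
  if (d == 0) {
    return(list(dip = 0, p_original = 1, p_calibrated = 1, n = n))
  }
  with_seed(seed, {
    null_u <- dip_null_cpp(n, n_mc, runif(as.numeric(n_mc) * n))
    null_g <- dip_null_cpp(n, n_mc,
                           rnorm(as.numeric(n_mc) * n, mean(x), sd(x)))
  })
  list(dip = d,
       p_original = (sum(null_u >= d) + 1) / (n_mc + 1),
       p_calibrated = (sum(null_g >= d) + 1) / (n_mc + 1),
       n = n)
}

#' Fit 1- and 2-component Gaussian mixtures and derive class cutoffs
#'
#' Fits univariate Gaussian mixtures with 1 and 2 unequal-variance
#' components by maximum likelihood, reports AIC/BIC for both, and places
#' two cutoffs on the trough-to-peak axis: the largest duration where the
#' posterior probability of the narrow component is at least `ratio` times
#' the broad one (`cutoff_low`), and the smallest duration where the broad
#' posterior is at least `ratio` times the narrow one (`cutoff_high`).
#' The narrow component is by definition the one with the smaller mean.
#'
#' @param t2p Trough-to-peak durations (ms).
#' @param ratio Posterior odds ratio defining the cutoffs.
#' @param grid_us Cutoff search grid resolution (microseconds).
#' @return List with cutoffs, mixture parameters, posterior matrix,
#'   AIC/BIC for both models and the preferred component count.
#' @export
fit_mixture_and_cutoffs <- function(t2p, ratio = 10, grid_us = 1) {
  stopifnot(length(t2p) >= 10)
  n <- length(t2p)
  # 1-component ML fit in closed form (mean, ML variance; 2 parameters)
  s2_ml <- mean((t2p - mean(t2p))^2)
  ll1 <- sum(dnorm(t2p, mean(t2p), sqrt(s2_ml), log = TRUE))
  f2 <- mclust::densityMclust(t2p, G = 2, modelNames = "V", plot = FALSE,
                              verbose = FALSE)
  if (is.null(f2) || f2$G != 2) stop("2-component EM fit failed")
  crit1 <- c(aic = -2 * ll1 + 2 * 2, bic = -2 * ll1 + log(n) * 2)
  crit2 <- c(aic = -2 * f2$loglik + 2 * f2$df,
             bic = -2 * f2$loglik + log(n) * f2$df)
  mu <- f2$parameters$mean
  sigma <- sqrt(f2$parameters$variance$sigmasq)
  if (length(sigma) == 1) sigma <- rep(sigma, 2)
  pro <- f2$parameters$pro
  if (abs(mu[1] - mu[2]) < 1e-8) stop("degenerate mixture: equal means")
  narrow <- which.min(mu)
  broad <- which.max(mu)

  grid <- seq(min(t2p), max(t2p), by = grid_us / 1000)
  post_n <- pro[narrow] * dnorm(grid, mu[narrow], sigma[narrow])
  post_b <- pro[broad] * dnorm(grid, mu[broad], sigma[broad])
  low_ok <- post_n >= ratio * post_b
  high_ok <- post_b >= ratio * post_n
  cutoff_low <- if (any(low_ok)) grid[max(which(low_ok))] else min(grid)
  cutoff_high <- if (any(high_ok)) grid[min(which(high_ok))] else max(grid)
  if (cutoff_low >= cutoff_high) {
    stop("cutoffs did not separate: mixture components overlap too much")
  }
  list(cutoff_low = cutoff_low, cutoff_high = cutoff_high,
       mean_narrow = mu[narrow], mean_broad = mu[broad],
       sd_narrow = sigma[narrow], sd_broad = sigma[broad],
       weight_narrow = pro[narrow],
       aic = c(g1 = unname(crit1["aic"]), g2 = unname(crit2["aic"])),
       bic = c(g1 = unname(crit1["bic"]), g2 = unname(crit2["bic"])),
       prefers_two = unname(crit2["aic"] < crit1["aic"] &
                              crit2["bic"] < crit1["bic"]),
       ratio = ratio)
}

#' Assign BW / NW / NC labels from trough-to-peak durations
#'
#' Durations at or below `cutoff_low` are narrow (NW), at or above
#' `cutoff_high` broad (BW); those strictly between the cutoffs are
#' unclassified (NC).
#'
#' @param t2p Durations (ms).
#' @param cutoffs List with `cutoff_low` and `cutoff_high` (e.g. from
#'   [fit_mixture_and_cutoffs()]).
#' @return Character vector of labels.
#' @export
assign_cell_types <- function(t2p, cutoffs) {
  stopifnot(cutoffs$cutoff_low < cutoffs$cutoff_high)
  ifelse(t2p <= cutoffs$cutoff_low, "NW",
         ifelse(t2p >= cutoffs$cutoff_high, "BW", "NC"))
}

#' Full waveform classification pipeline
#'
#' QC-filters the mean waveforms of a waveform table, measures
#' trough-to-peak durations on interpolated traces, tests bimodality, fits
#' the two-Gaussian mixture and labels every surviving unit.
#'
#' @param waveforms Long waveform table (unit_id, sample_idx, mean_v).
#' @param sampling_interval_us Raw sampling interval.
#' @param n_mc Dip-test Monte-Carlo iterations.
#' @param seed RNG seed for the dip test.
#' @return List with `assignments` (unit_id, t2p_ms, label, qc), `model`
#'   (mixture + cutoffs) and `dip` (bimodality test).
#' @export
classify_waveforms <- function(waveforms, sampling_interval_us = 25,
                               n_mc = 2000, seed = 1L) {
  by_unit <- split(waveforms, waveforms$unit_id)
  rows <- lapply(names(by_unit), function(u) {
    v <- by_unit[[u]]$mean_v[order(by_unit[[u]]$sample_idx)]
    qc <- qc_exclude(v)
    t2p <- if (qc$keep) {
      measure_trough_to_peak(v, sampling_interval_us)$t2p_ms
    } else NA_real_
    data.frame(unit_id = u, t2p_ms = t2p, qc_keep = qc$keep,
               qc_reason = qc$reason, stringsAsFactors = FALSE)
  })
  asn <- do.call(rbind, rows)
  ok <- asn$qc_keep
  dip <- test_bimodality(asn$t2p_ms[ok], n_mc = n_mc, seed = seed)
  model <- fit_mixture_and_cutoffs(asn$t2p_ms[ok])
  asn$label <- NA_character_
  asn$label[ok] <- assign_cell_types(asn$t2p_ms[ok], model)
  list(assignments = asn, model = model, dip = dip)
}

#' Baseline firing metrics per unit
#'
#' Firing rate, Fano factor (across-trial spike-count variance over mean)
#' and the interspike-interval coefficient of variation, computed in a
#' fixed epoch (default the 1 s fixation period) over completed trials.
#' ISIs are within-trial only; variances use n - 1.
#'
#' @param session A [pf_session()].
#' @param epoch Window in seconds relative to the alignment event.
#' @param align "fixation" or "is".
#' @param min_trials Minimum completed trials required per unit.
#' @return Data frame with unit_id, rate, fano, cv, n_trials (fano/cv `NA`
#'   when undefined).
#' @export
firing_metrics <- function(session, epoch = c(0, 1), align = "fixation",
                           min_trials = 30) {
  tr <- session$trials
  align_t <- if (align == "is") tr$is_onset_s else tr$fixation_onset_s
  a <- align_t + epoch[1]
  b <- align_t + epoch[2]
  dur <- epoch[2] - epoch[1]
  sp <- split(session$spikes, factor(session$spikes$unit_id,
                                     levels = session$units$unit_id))
  rows <- lapply(session$units$unit_id, function(u) {
    su <- sp[[u]]
    nt <- nrow(tr)
    if (nt < min_trials) {
      return(data.frame(unit_id = u, rate = NA_real_, fano = NA_real_,
                        cv = NA_real_, n_trials = nt))
    }
    counts <- numeric(nt)
    isis <- list()
    for (ti in seq_len(nt)) {
      s <- su$t_s[su$trial_id == tr$trial_id[ti]]
      s <- sort(s[s >= a[ti] & s < b[ti]])
      counts[ti] <- length(s)
      if (length(s) >= 2) isis[[length(isis) + 1]] <- diff(s)
    }
    isi <- unlist(isis)
    mu_c <- mean(counts)
    data.frame(
      unit_id = u,
      rate = sum(counts) / (nt * dur),
      fano = if (mu_c > 0) var(counts) / mu_c else NA_real_,
      cv = if (length(isi) >= 2) sd(isi) / mean(isi) else NA_real_,
      n_trials = nt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
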