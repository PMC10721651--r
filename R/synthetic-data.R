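#' Configuration for the synthetic-session generator
#'
#' Bundles and validates every knob of the generator.  Defaults describe a
#' realistic single recording day: a 3:1 mix of broad-spiking (BW, putative
#' pyramidal) and narrow-spiking (NW, putative interneuron) units, low
#' baseline rates for BW and higher ones for NW, a bimodal trough-to-peak
#' geometry, three-condition task variables, a 1 s fixation epoch and an
#' instruction-stimulus (IS) period of 1/1.5/2 s, and a Bernoulli learner
#' with a performance change-point.
#'
#' @param n_units_bw,n_units_nw Unit counts per waveform class.
#' @param rate_bw,rate_nw Mean baseline firing rates (spikes/s).
#' @param t2p_bw_mean,t2p_bw_sd,t2p_nw_mean,t2p_nw_sd Trough-to-peak
#'   duration mixture parameters (ms); the NW mean must be below the BW
#'   mean.
#' @param selectivity_profile One of "none", "static", "transient",
#'   "switching".
#' @param effect_size Multiplicative rate modulation for the preferred
#'   condition (>= 0; 1 means no modulation).
#' @param transient_window IS-relative window (s) carrying the modulation
#'   for the "transient" profile.
#' @param switch_time IS-relative time (s) at which the preferred
#'   condition swaps for the "switching" profile.
#' @param n_trials Number of trials in the session.
#' @param task One of "strategy", "novelmap", "fammap".
#' @param learner List with `p_pre`, `p_post` (correct probabilities) and
#'   `change_trial` (1-based trial from which `p_post` applies).
#' @param gamma_shape Shape of the gamma renewal process (1 = Poisson).
#' @param rate_dispersion Across-unit rate heterogeneity: rates are drawn
#'   from a gamma distribution with this shape around the class mean (larger
#'   = more homogeneous).
#' @param contamination_fraction Fraction of units whose waveform violates
#'   the amplitude QC rules (axon-like shapes), for testing QC.
#' @param seed Master RNG seed; split into named streams internally.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_units_bw = 24, n_units_nw = 8,
                         rate_bw = 2.1, rate_nw = 5.1,
                         t2p_bw_mean = 0.42, t2p_bw_sd = 0.07,
                         t2p_nw_mean = 0.18, t2p_nw_sd = 0.04,
                         selectivity_profile = c("none", "static",
                                                 "transient", "switching"),
                         effect_size = 1,
                         transient_window = c(0, 0.5),
                         switch_time = 0.5,
                         n_trials = 150,
                         task = c("novelmap", "fammap", "strategy"),
                         learner = list(p_pre = 1 / 3, p_post = 0.95,
                                        change_trial = 16),
                         gamma_shape = 1,
                         rate_dispersion = 4,
                         contamination_fraction = 0,
                         seed = 1L) {
  selectivity_profile <- match.arg(selectivity_profile)
  task <- match.arg(task)
  stopifnot(
    n_units_bw >= 0, n_units_nw >= 0, n_units_bw + n_units_nw >= 1,
    rate_bw > 0, rate_nw > 0,
    t2p_bw_mean > 0, t2p_nw_mean > 0,
    t2p_bw_sd > 0, t2p_nw_sd > 0,
    effect_size >= 0, n_trials >= 1,
    gamma_shape > 0, rate_dispersion > 0,
    contamination_fraction >= 0, contamination_fraction <= 1,
    length(transient_window) == 2, transient_window[1] < transient_window[2],
    switch_time > 0
  )
  if (t2p_nw_mean >= t2p_bw_mean) {
    stop("NW trough-to-peak mean must be smaller than the BW mean")
  }
  stopifnot(is.list(learner),
            learner$p_pre >= 0, learner$p_pre <= 1,
            learner$p_post >= 0, learner$p_post <= 1,
            learner$change_trial >= 1)
  if (learner$change_trial > n_trials + 1) {
    stop("learner change_trial must be <= n_trials + 1")
  }
  structure(list(
    n_units_bw = as.integer(n_units_bw), n_units_nw = as.integer(n_units_nw),
    rate_bw = rate_bw, rate_nw = rate_nw,
    t2p_bw_mean = t2p_bw_mean, t2p_bw_sd = t2p_bw_sd,
    t2p_nw_mean = t2p_nw_mean, t2p_nw_sd = t2p_nw_sd,
    selectivity_profile = selectivity_profile, effect_size = effect_size,
    transient_window = transient_window, switch_time = switch_time,
    n_trials = as.integer(n_trials), task = task, learner = learner,
    gamma_shape = gamma_shape, rate_dispersion = rate_dispersion,
    contamination_fraction = contamination_fraction,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# per-unit ground-truth table: class, t2p, baseline rate, preferred
# condition and profile
generate_unit_truth <- function(config) {
  n <- config$n_units_bw + config$n_units_nw
  cls <- rep(c("BW", "NW"), c(config$n_units_bw, config$n_units_nw))
  with_seed(stream_seed(config$seed, "units"), {
    t2p <- ifelse(cls == "BW",
                  rnorm(n, config$t2p_bw_mean, config$t2p_bw_sd),
                  rnorm(n, config$t2p_nw_mean, config$t2p_nw_sd))
    t2p <- pmax(t2p, 0.05) # physical floor, two raw samples
    shape <- config$rate_dispersion
    rate <- ifelse(cls == "BW",
                   rgamma(n, shape = shape, rate = shape / config$rate_bw),
                   rgamma(n, shape = shape, rate = shape / config$rate_nw))
    rate <- pmax(rate, 0.05)
    pref <- sample.int(3, n, replace = TRUE)
    contaminated <- runif(n) < config$contamination_fraction
  })
  data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    class = cls,
    t2p_ms = t2p,
    baseline_rate = rate,
    preferred_condition = pref,
    profile = config$selectivity_profile,
    contaminated = contaminated,
    stringsAsFactors = FALSE
  )
}

# difference-of-Gaussians bump waveform: small positive pre-peak, main
# trough (amplitude 1), positive post-peak at trough + t2p.  Lobe widths
# scale with t2p so the post-trough maximum lands within one raw sample of
# the drawn t2p.
waveform_shape <- function(t_ms, t2p_ms, trough_ms = 0.5,
                           post_amp = 0.4, pre_amp = 0.15,
                           axon_like = FALSE) {
  s1 <- 0.25 * t2p_ms
  s2 <- 0.35 * t2p_ms
  if (axon_like) post_amp <- 1.3 # violates |trough| >= |post-peak|
  -dnorm(t_ms, trough_ms, s1) / dnorm(0, 0, s1) +
    post_amp * dnorm(t_ms, trough_ms + t2p_ms, s2) / dnorm(0, 0, s2) +
    pre_amp * dnorm(t_ms, trough_ms - 1.4 * t2p_ms, s2) / dnorm(0, 0, s2)
}

#' Generate mean waveforms with a two-Gaussian trough-to-peak mixture
#'
#' Produces per-unit mean voltage traces sampled at 25 microseconds whose
#' trough-to-peak durations follow the configured two-Gaussian mixture.
#' Each trace has a single main trough followed by a positive peak whose
#' distance from the trough equals the unit's drawn duration to within one
#' raw sample.  Amplitudes pass the [qc_exclude()] rules unless a
#' contamination fraction is configured.
#'
#' @param config A [synth_config()].
#' @param noise_sd Gaussian noise added to each sample (arbitrary units;
#'   trough amplitude is 1).
#' @return List with `waveforms` (long data frame: unit_id, sample_idx,
#'   mean_v, sd_v) and `truth` (per-unit ground-truth table).
#' @export
generate_waveforms <- function(config, noise_sd = 0.005) {
  truth <- generate_unit_truth(config)
  dt_ms <- 0.025 # 25 us raw sampling
  n_samp <- 72L  # 1.8 ms window
  t_ms <- (seq_len(n_samp) - 1) * dt_ms
  with_seed(stream_seed(config$seed, "waveforms"), {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      v <- waveform_shape(t_ms, truth$t2p_ms[i],
                          axon_like = truth$contaminated[i])
      v <- v + rnorm(n_samp, 0, noise_sd)
      data.frame(unit_id = truth$unit_id[i],
                 sample_idx = seq_len(n_samp),
                 mean_v = v,
                 sd_v = rep(noise_sd * 20 + 0.05, n_samp),
                 stringsAsFactors = FALSE)
    })
  })
  list(waveforms = do.call(rbind, rows), truth = truth)
}

#' Generate a binary correctness sequence from a step learner
#'
#' Trial `t` is correct with probability `p_pre` for `t < change_trial` and
#' `p_post` from `change_trial` onwards.
#'
#' @param learner List with `p_pre`, `p_post`, `change_trial`.
#' @param n_trials Number of trials.
#' @param seed RNG seed.
#' @return Integer vector of 0/1 of length `n_trials`.
#' @export
generate_behavior_sequence <- function(learner, n_trials, seed = 1L) {
  stopifnot(learner$change_trial <= n_trials + 1)
  p <- ifelse(seq_len(n_trials) < learner$change_trial,
              learner$p_pre, learner$p_post)
  with_seed(seed, as.integer(rbinom(n_trials, 1L, p)))
}

# trial table shared by the three tasks: 1 s fixation, IS of 1/1.5/2 s
generate_trial_table <- function(config) {
  n <- config$n_trials
  with_seed(stream_seed(config$seed, "trials"), {
    is_dur <- sample(c(1, 1.5, 2), n, replace = TRUE)
    stim <- sample.int(3, n, replace = TRUE)
    if (config$task == "strategy") {
      # repeat trial: same IS as previous -> stay; change trial -> shift
      resp <- integer(n)
      resp[1] <- sample.int(3, 1)
      for (t in 2:n) {
        resp[t] <- if (stim[t] == stim[t - 1]) resp[t - 1] else
          sample(setdiff(1:3, resp[t - 1]), 1)
      }
      assoc <- rep(NA_integer_, n)
      correct <- as.integer(runif(n) < 0.98)
    } else {
      # fixed stimulus -> response mapping; association id = stimulus id
      mapping <- if (config$task == "fammap") 1:3 else sample(1:3)
      resp <- mapping[stim]
      assoc <- stim
      correct <- generate_behavior_sequence(config$learner, n,
                                            stream_seed(config$seed,
                                                        "behavior"))
    }
  })
  targets <- c("top", "right", "left")
  data.frame(
    trial_id = seq_len(n),
    stimulus_id = stim,
    response_target = targets[resp],
    association_id = assoc,
    correct = correct == 1L,
    correction = FALSE,
    fixation_onset_s = 0,
    is_onset_s = 1,
    is_duration_s = is_dur,
    go_s = 1 + is_dur,
    stringsAsFactors = FALSE
  )
}

# condition value (1..3) per trial for the variable the generator modulates
condition_of <- function(trials, task) {
  if (task == "strategy") trials$stimulus_id else trials$association_id
}

# piecewise-constant rate for one unit on one trial, as break times (s,
# relative to fixation onset) and rates on each piece
unit_rate_profile <- function(config, base, pref_match, pref_match_late,
                              is_onset, is_dur) {
  eff <- config$effect_size
  profile <- config$selectivity_profile
  if (profile == "none" || eff == 1) {
    return(list(breaks = c(0, is_onset + is_dur + 1), rates = base))
  }
  mod <- base * eff
  if (mod < 0) stop("negative modulated rate")
  if (profile == "static") {
    breaks <- c(0, is_onset, is_onset + is_dur, is_onset + is_dur + 1)
    rates <- c(base, if (pref_match) mod else base, base)
  } else if (profile == "transient") {
    w <- config$transient_window
    breaks <- c(0, is_onset + w[1], is_onset + w[2], is_onset + is_dur + 1)
    rates <- c(base, if (pref_match) mod else base, base)
  } else { # switching: preference swaps at switch_time within the IS
    st <- config$switch_time
    breaks <- c(0, is_onset, is_onset + st, is_onset + is_dur,
                is_onset + is_dur + 1)
    rates <- c(base,
               if (pref_match) mod else base,
               if (pref_match_late) mod else base,
               base)
  }
  keep <- diff(breaks) > 0 # drop zero-length pieces, keep break/rate pairing
  list(breaks = c(breaks[-length(breaks)][keep], breaks[length(breaks)]),
       rates = rates[keep])
}

# draw renewal-process spikes on [0, tmax) with piecewise-constant rate via
# time rescaling: unit-rate gamma renewal in operational time
draw_renewal <- function(breaks, rates, shape) {
  tmax <- breaks[length(breaks)]
  durs <- diff(breaks)
  total_op <- sum(durs * rates) # operational time budget
  if (total_op <= 0) return(numeric(0))
  n_guess <- max(10, ceiling(total_op + 4 * sqrt(total_op / shape) + 10))
  isi <- rgamma(n_guess, shape = shape, rate = shape)
  op <- cumsum(isi)
  while (op[length(op)] < total_op) {
    isi2 <- rgamma(n_guess, shape = shape, rate = shape)
    op <- c(op, op[length(op)] + cumsum(isi2))
  }
  op <- op[op < total_op]
  if (!length(op)) return(numeric(0))
  # map operational time back to real time through the piecewise rate
  cum_op <- c(0, cumsum(durs * rates))
  piece <- findInterval(op, cum_op, rightmost.closed = TRUE)
  breaks[piece] + (op - cum_op[piece]) / rates[piece]
}

#' Generate spike trains for a trial table
#'
#' Spikes are drawn from a (gamma-)renewal process whose rate during the IS
#' period is `baseline * effect_size` for a unit's preferred condition.
#' The `static` profile applies the modulation across the whole IS period,
#' `transient` only within `transient_window`, and `switching` swaps the
#' preferred condition at `switch_time`.
#'
#' @param config A [synth_config()].
#' @param trial_table Trial table as produced by [generate_session()] (needs
#'   condition labels and event times).
#' @param truth Optional per-unit ground-truth table; generated from the
#'   config when omitted.
#' @return List with `spikes` (unit_id, trial_id, t_s; times relative to
#'   fixation onset) and `truth`.
#' @export
generate_spike_trains <- function(config, trial_table, truth = NULL) {
  if (is.null(truth)) truth <- generate_unit_truth(config)
  cond <- condition_of(trial_table, config$task)
  with_seed(stream_seed(config$seed, "spikes"), {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      u <- truth[i, ]
      pref_late <- (u$preferred_condition %% 3L) + 1L # switching target
      per_trial <- lapply(seq_len(nrow(trial_table)), function(t) {
        tr <- trial_table[t, ]
        prof <- unit_rate_profile(
          config, u$baseline_rate,
          pref_match = identical(cond[t], u$preferred_condition),
          pref_match_late = identical(cond[t], pref_late),
          is_onset = tr$is_onset_s - tr$fixation_onset_s,
          is_dur = tr$is_duration_s
        )
        s <- draw_renewal(prof$breaks, prof$rates, config$gamma_shape)
        if (length(s)) data.frame(unit_id = u$unit_id, trial_id = tr$trial_id,
                                  t_s = s, stringsAsFactors = FALSE)
      })
      out[[i]] <- do.call(rbind, per_trial)
    }
  })
  spikes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(spikes)) {
    spikes <- data.frame(unit_id = character(), trial_id = integer(),
                         t_s = numeric(), stringsAsFactors = FALSE)
  }
  rownames(spikes) <- NULL
  list(spikes = spikes, truth = truth)
}

#' Generate a full synthetic session with ground truth
#'
#' Assembles the trial table (1 s fixation, IS duration drawn from
#' 1/1.5/2 s, three-level condition labels, task-appropriate
#' stimulus-response structure and correctness), per-unit waveforms and
#' spike trains into a [pf_session()] plus its ground truth.
#'
#' @param config A [synth_config()].
#' @return List with `session` (class `pf_session`) and `truth` (per-unit
#'   ground truth plus the session-level `change_trial`).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  trials <- generate_trial_table(config)
  wf <- generate_waveforms(config)
  sp <- generate_spike_trains(config, trials, truth = wf$truth)
  units <- data.frame(unit_id = wf$truth$unit_id,
                      tasks = config$task,
                      curated = TRUE,
                      stringsAsFactors = FALSE)
  session <- pf_session(
    session_id = sprintf("synth-%s-seed%d", config$task, config$seed),
    task = config$task,
    trials = trials,
    spikes = sp$spikes,
    waveforms = wf$waveforms,
    units = units,
    sampling_interval_us = 25,
    metadata = list(generator = "popcoding synthetic", seed = config$seed)
  )
  truth <- wf$truth
  attr(truth, "change_trial") <- config$learner$change_trial
  list(session = session, truth = truth)
}
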