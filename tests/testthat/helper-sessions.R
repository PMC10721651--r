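# Shared fixtures: small synthetic sessions and IS-period tensors, built
# in code.  Expensive objects are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

make_session <- function(profile = "none", effect = 1, n_bw = 10, n_nw = 4,
                         n_trials = 90, task = "novelmap", seed = 1,
                         ...) {
  cfg <- synth_config(n_units_bw = n_bw, n_units_nw = n_nw,
                      selectivity_profile = profile, effect_size = effect,
                      n_trials = n_trials, task = task, seed = seed, ...)
  generate_session(cfg)
}

# IS-period tensor restricted to correct trials, plus condition labels
is_tensor <- function(session, variable = "association_id",
                      window = c(0, 1), width_ms = 50, step_ms = 50) {
  tens <- bin_spikes(session, align = "is", window = window,
                     width_ms = width_ms, step_ms = step_ms)
  keep <- session$trials$correct & !session$trials$correction
  tens$counts <- tens$counts[, keep, , drop = FALSE]
  list(tensor = tens, labels = session$trials[[variable]][keep])
}

# a decoded static-profile population shared by stability tests
static_decode_fixture <- function() {
  cached("static_decode", {
    gs <- make_session("static", effect = 3, n_bw = 28, n_nw = 12,
                       n_trials = 120, seed = 7)
    d <- is_tensor(gs$session)
    dec <- cross_temporal_decode(d$tensor, d$labels, folds = 10, runs = 5,
                                 shuffles = 420, seed = 2)
    list(dec = dec, labels = d$labels, tensor = d$tensor)
  })
}

# hand-built session: one unit, explicit spike times per trial
manual_session <- function(spike_times_by_trial, n_trials = NULL,
                           is_duration = 1.5) {
  nt <- if (is.null(n_trials)) length(spike_times_by_trial) else n_trials
  trials <- data.frame(
    trial_id = seq_len(nt),
    stimulus_id = rep_len(1:3, nt),
    response_target = rep_len(c("top", "right", "left"), nt),
    association_id = rep_len(1:3, nt),
    correct = TRUE, correction = FALSE,
    fixation_onset_s = 0, is_onset_s = 1,
    is_duration_s = is_duration, go_s = 1 + is_duration
  )
  spikes <- do.call(rbind, lapply(seq_along(spike_times_by_trial),
    function(t) {
      s <- spike_times_by_trial[[t]]
      if (!length(s)) return(NULL)
      data.frame(unit_id = "u001", trial_id = t, t_s = s)
    }))
  if (is.null(spikes)) {
    spikes <- data.frame(unit_id = character(), trial_id = integer(),
                         t_s = numeric())
  }
  pf_session(session_id = "manual", task = "novelmap", trials = trials,
             spikes = spikes,
             waveforms = data.frame(unit_id = character(),
                                    sample_idx = integer(),
                                    mean_v = numeric(), sd_v = numeric()),
             units = data.frame(unit_id = "u001", tasks = "novelmap"))
}
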