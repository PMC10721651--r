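test_that("config validation rejects inconsistent parameters", {
  expect_error(synth_config(t2p_nw_mean = 0.5, t2p_bw_mean = 0.4),
               "smaller than the BW mean")
  expect_error(synth_config(rate_bw = 0), "rate_bw")
  expect_error(synth_config(n_trials = 10,
                            learner = list(p_pre = 0.3, p_post = 0.9,
                                           change_trial = 20)),
               "change_trial")
  expect_error(synth_config(learner = list(p_pre = 1.2, p_post = 0.9,
                                           change_trial = 2)))
})

test_that("waveform trough-to-peak geometry matches the drawn duration", {
  cfg <- synth_config(n_units_bw = 15, n_units_nw = 15, n_trials = 5,
                      learner = list(p_pre = 1, p_post = 1,
                                     change_trial = 1), seed = 3)
  wf <- generate_waveforms(cfg, noise_sd = 0.002)
  by_unit <- split(wf$waveforms, wf$waveforms$unit_id)
  for (u in wf$truth$unit_id) {
    v <- by_unit[[u]]$mean_v[order(by_unit[[u]]$sample_idx)]
    trough <- which.min(v)
    peak <- trough + which.max(v[(trough + 1):length(v)])
    raw_t2p <- (peak - trough) * 0.025
    expect_lte(abs(raw_t2p - wf$truth$t2p_ms[wf$truth$unit_id == u]),
               0.025 + 1e-9)
  }
})

test_that("contamination controls QC pass rate by construction", {
  base <- list(n_trials = 5,
               learner = list(p_pre = 1, p_post = 1, change_trial = 1))
  clean <- generate_waveforms(synth_config(n_units_bw = 20, n_units_nw = 8,
    n_trials = 5, learner = base$learner, contamination_fraction = 0,
    seed = 4))
  dirty <- generate_waveforms(synth_config(n_units_bw = 20, n_units_nw = 8,
    n_trials = 5, learner = base$learner, contamination_fraction = 1,
    seed = 4))
  keep_of <- function(wf) {
    vapply(split(wf$waveforms, wf$waveforms$unit_id), function(d) {
      qc_exclude(d$mean_v[order(d$sample_idx)])$keep
    }, logical(1))
  }
  expect_true(all(keep_of(clean)))
  expect_false(any(keep_of(dirty)))
})

test_that("trough-to-peak mixture reproduces its generator parameters", {
  cfg <- synth_config(n_units_bw = 910, n_units_nw = 390, n_trials = 5,
                      learner = list(p_pre = 1, p_post = 1,
                                     change_trial = 1), seed = 5)
  tr <- popcoding:::generate_unit_truth(cfg)
  for (cls in c("BW", "NW")) {
    t2p <- tr$t2p_ms[tr$class == cls]
    mu <- if (cls == "BW") cfg$t2p_bw_mean else cfg$t2p_nw_mean
    sg <- if (cls == "BW") cfg$t2p_bw_sd else cfg$t2p_nw_sd
    expect_lte(abs(mean(t2p) - mu), 3 * sg / sqrt(length(t2p)))
  }
  expect_identical(sum(tr$class == "BW"), 910L)
  expect_identical(sum(tr$class == "NW"), 390L)
})

test_that("behavior sequences follow the step learner", {
  expect_equal(generate_behavior_sequence(list(p_pre = 1, p_post = 1,
                                               change_trial = 5), 20),
               rep(1L, 20))
  s <- generate_behavior_sequence(list(p_pre = 0, p_post = 1,
                                       change_trial = 10), 20)
  expect_equal(s, c(rep(0L, 9), rep(1L, 11)))
  # Monte-Carlo check of the pre/post means
  pre <- post <- numeric(400)
  for (i in 1:400) {
    x <- generate_behavior_sequence(list(p_pre = 1 / 3, p_post = 0.95,
                                         change_trial = 101), 200,
                                    seed = i)
    pre[i] <- mean(x[1:100])
    post[i] <- mean(x[101:200])
  }
  se_pre <- sqrt(1 / 3 * 2 / 3 / (100 * 400))
  se_post <- sqrt(0.95 * 0.05 / (100 * 400))
  expect_lte(abs(mean(pre) - 1 / 3), 3 * se_pre)
  expect_lte(abs(mean(post) - 0.95), 3 * se_post)
})

test_that("spike modulation follows the selectivity profile", {
  rate_by_cond <- function(gs, window) {
    s <- gs$session
    tens <- bin_spikes(s, align = "is", window = window,
                       width_ms = 1000 * diff(window),
                       step_ms = 1000 * diff(window))
    cond <- s$trials$association_id
    truth <- gs$truth
    vapply(1:3, function(cv) {
      mean(tens$rates[, cond == cv, 1], na.rm = TRUE)
    }, numeric(1))
  }
  # null case: no modulation
  gs0 <- make_session("none", effect = 1, n_bw = 8, n_nw = 0,
                      n_trials = 150, seed = 11)
  r0 <- rate_by_cond(gs0, c(0, 1))
  pooled <- mean(r0)
  expect_lt(max(abs(r0 - pooled)), 3 * pooled / sqrt(50 * 8))
  # static: preferred condition elevated in both halves of the IS
  cfg <- synth_config(n_units_bw = 1, n_units_nw = 0, rate_bw = 5,
                      selectivity_profile = "static", effect_size = 3,
                      rate_dispersion = 1e6, n_trials = 300, seed = 12)
  gs <- generate_session(cfg)
  pref <- gs$truth$preferred_condition[1]
  for (w in list(c(0, 0.5), c(0.5, 1))) {
    r <- rate_by_cond(gs, w)
    expect_gt(r[pref], max(r[-pref]))
  }
  # switching: preference differs between the two halves
  cfg2 <- synth_config(n_units_bw = 1, n_units_nw = 0, rate_bw = 5,
                       selectivity_profile = "switching", effect_size = 3,
                       switch_time = 0.5, rate_dispersion = 1e6,
                       n_trials = 300, seed = 13)
  gs2 <- generate_session(cfg2)
  early <- rate_by_cond(gs2, c(0, 0.5))
  late <- rate_by_cond(gs2, c(0.5, 1))
  expect_false(which.max(early) == which.max(late))
})

test_that("session structure follows the task rules", {
  # fammap: each stimulus maps to exactly one response target
  fam <- make_session(task = "fammap", seed = 21,
                      learner = list(p_pre = 1, p_post = 1,
                                     change_trial = 1))$session
  maps <- unique(fam$trials[c("stimulus_id", "response_target")])
  expect_identical(nrow(maps), 3L)
  # strategy: no fixed stimulus -> response mapping exists
  str <- make_session(task = "strategy", n_trials = 150,
                      seed = 22)$session
  maps2 <- unique(str$trials[c("stimulus_id", "response_target")])
  expect_gt(nrow(maps2), 3)
  # repeat trials keep the previous response
  tr <- str$trials
  rep_tr <- which(tr$stimulus_id[-1] == tr$stimulus_id[-nrow(tr)]) + 1
  expect_true(all(tr$response_target[rep_tr] ==
                    tr$response_target[rep_tr - 1]))
  expect_true(all(fam$trials$is_duration_s %in% c(1, 1.5, 2)))
})

test_that("generation is reproducible and roundtrips through disk", {
  gs1 <- make_session("static", effect = 2, n_bw = 4, n_nw = 2,
                      n_trials = 40, seed = 33)
  gs2 <- make_session("static", effect = 2, n_bw = 4, n_nw = 2,
                      n_trials = 40, seed = 33)
  expect_identical(gs1$session$spikes, gs2$session$spikes)
  expect_identical(gs1$truth, gs2$truth)
  dir <- withr::local_tempdir()
  write_session(gs1$session, dir)
  back <- read_session(dir)
  expect_equal(back$trials, gs1$session$trials)
  expect_equal(back$spikes, gs1$session$spikes, tolerance = 1e-12)
  expect_equal(back$waveforms, gs1$session$waveforms, tolerance = 1e-12)
  expect_identical(back$task, gs1$session$task)
})
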