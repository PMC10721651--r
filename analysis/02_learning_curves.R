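#!/usr/bin/env Rscript
# Behavioral analysis: moving-average performance curves, the binomial
# learning-completion trial for a batch of simulated NovelMap learners,
# and the learning / post-learning block split of the session generated
# in step 01.  Writes results/learning.json and
# results/performance_curve.csv.

suppressPackageStartupMessages(library(popcoding))

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

# learning-point distribution across 200 simulated sessions
k_hat <- vapply(1:200, function(i) {
  n <- generate_behavior_sequence(
    list(p_pre = 1 / 3, p_post = 0.95, change_trial = 16), 120,
    seed = stream_seed(seed, paste0("learner", i)))
  as.numeric(estimate_learning_trial(n))
}, numeric(1))
cat(sprintf("learning completed at median trial %g (IQR %g-%g)\n",
            median(k_hat, na.rm = TRUE),
            quantile(k_hat, 0.25, na.rm = TRUE),
            quantile(k_hat, 0.75, na.rm = TRUE)))

# block split of the simulated NovelMap session
sess <- read_session("results/sessions/novelmap")
k <- estimate_learning_trial(as.integer(sess$trials$correct),
                             min_trials = 42)
blocks <- split_blocks(sess, k)
cat(sprintf("NovelMap session: k = %d, learning block %d trials, ",
            k, length(blocks$learning)),
    sprintf("post-learning %d trials\n", length(blocks$post_learning)))

# across-session performance curve over the first 50 trials
sessions <- lapply(1:12, function(i) {
  cfg <- synth_config(n_units_bw = 1, n_units_nw = 0, n_trials = 60,
                      task = "novelmap",
                      seed = stream_seed(seed, paste0("curve", i)))
  generate_session(cfg)$session
})
curve <- performance_curve(sessions, first_trials = 50)
write.csv(curve, "results/performance_curve.csv", row.names = FALSE)

jsonlite::write_json(
  list(median_learning_trial = median(k_hat, na.rm = TRUE),
       novelmap_k = k,
       learning_block_trials = length(blocks$learning),
       post_learning_trials = length(blocks$post_learning)),
  "results/learning.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/learning.json, results/performance_curve.csv\n")
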