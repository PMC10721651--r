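#!/usr/bin/env Rscript
# Generate the synthetic recording sessions used by the downstream
# analysis steps: a NovelMap session with a step learner (associations
# learned around trial 16), a FamMap session with near-ceiling
# performance, and a Strategy session, each with a mixed population of
# broad- (putative pyramidal) and narrow-spiking (putative interneuron)
# units.  Sessions are written in the on-disk session format under
# results/sessions/ together with the generator ground truth.

suppressPackageStartupMessages(library(popcoding))

seed <- 20260927L
out <- "results/sessions"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

configs <- list(
  novelmap = synth_config(n_units_bw = 24, n_units_nw = 8,
                          selectivity_profile = "static",
                          effect_size = 2.5, n_trials = 150,
                          task = "novelmap",
                          seed = stream_seed(seed, "novelmap")),
  fammap = synth_config(n_units_bw = 24, n_units_nw = 8,
                        selectivity_profile = "static",
                        effect_size = 2.5, n_trials = 150,
                        task = "fammap",
                        learner = list(p_pre = 0.98, p_post = 0.98,
                                       change_trial = 1),
                        seed = stream_seed(seed, "fammap")),
  strategy = synth_config(n_units_bw = 24, n_units_nw = 8,
                          selectivity_profile = "static",
                          effect_size = 2.5, n_trials = 150,
                          task = "strategy",
                          seed = stream_seed(seed, "strategy"))
)

for (nm in names(configs)) {
  gs <- generate_session(configs[[nm]])
  dir <- file.path(out, nm)
  write_session(gs$session, dir)
  write.csv(gs$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  cat(sprintf("%-9s %3d trials, %2d units, %6d spikes -> %s\n", nm,
              nrow(gs$session$trials), nrow(gs$session$units),
              nrow(gs$session$spikes), dir))
}
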