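#!/usr/bin/env Rscript
# Waveform-based cell-type classification: trough-to-peak durations from
# interpolated mean waveforms, dip-test bimodality, two-Gaussian mixture
# cutoffs, BW/NW/NC labels, and baseline firing metrics per class.  Runs
# on a large simulated unit database (pooling across tasks mirrors the
# pooled classification) and on the step-01 sessions.  Writes
# results/celltypes.csv and results/celltype_model.json.

suppressPackageStartupMessages(library(popcoding))

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

# pooled database of 1300 units for the mixture fit
cfg <- synth_config(n_units_bw = 975, n_units_nw = 325, n_trials = 20,
                    learner = list(p_pre = 1 / 3, p_post = 0.95,
                                   change_trial = 5),
                    seed = stream_seed(seed, "celltypes"))
wf <- generate_waveforms(cfg)
cl <- classify_waveforms(wf$waveforms, n_mc = 2000,
                         seed = stream_seed(seed, "dip"))

tab <- table(cl$assignments$label)
cat(sprintf("dip test: p_original = %.4f, p_calibrated = %.4f\n",
            cl$dip$p_original, cl$dip$p_calibrated))
cat(sprintf("AIC %0.f -> %0.f, BIC %0.f -> %0.f (1 -> 2 components)\n",
            cl$model$aic[["g1"]], cl$model$aic[["g2"]],
            cl$model$bic[["g1"]], cl$model$bic[["g2"]]))
cat(sprintf("cutoffs %.3f / %.3f ms; labels: %s\n",
            cl$model$cutoff_low, cl$model$cutoff_high,
            paste(names(tab), tab, collapse = ", ")))

m <- merge(cl$assignments, wf$truth[, c("unit_id", "class")],
           by = "unit_id")
non_nc <- m$label %in% c("BW", "NW")
cat(sprintf("ground-truth agreement on classified units: %.1f%%\n",
            100 * mean(m$label[non_nc] == m$class[non_nc])))

write.csv(cl$assignments, "results/celltypes.csv", row.names = FALSE)
jsonlite::write_json(
  list(cutoff_low_ms = cl$model$cutoff_low,
       cutoff_high_ms = cl$model$cutoff_high,
       dip = cl$dip[c("dip", "p_original", "p_calibrated")],
       aic = as.list(cl$model$aic), bic = as.list(cl$model$bic),
       counts = as.list(tab)),
  "results/celltype_model.json", auto_unbox = TRUE, digits = NA)

# firing metrics by class on the NovelMap session from step 01
sess <- read_session("results/sessions/novelmap")
truth <- read.csv("results/sessions/novelmap/ground_truth.csv")
fm <- merge(firing_metrics(sess, min_trials = 30),
            truth[, c("unit_id", "class")], by = "unit_id")
agg <- aggregate(cbind(rate, fano, cv) ~ class, fm, median)
print(agg, row.names = FALSE)
write.csv(fm, "results/firing_metrics.csv", row.names = FALSE)
cat("wrote results/celltypes.csv, results/celltype_model.json,",
    "results/firing_metrics.csv\n")
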