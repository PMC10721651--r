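#!/usr/bin/env Rscript
# Omega-squared selectivity time courses (150 ms bins stepped by 15 ms,
# 50 balanced trial subsamples), population onset latencies against a
# label-shuffle null, epoch-wise selective-cell percentages, and the
# population control filters (rate matching, task-relatedness, low-rate
# exclusion).  Writes results/omega_timecourse.csv and
# results/selectivity.json.

suppressPackageStartupMessages(library(popcoding))

seed <- 20260927L
dir.create("results", showWarnings = FALSE)

sess <- read_session("results/sessions/novelmap")
truth <- read.csv("results/sessions/novelmap/ground_truth.csv")
keep_units <- filter_units_by_trials(sess, "association_id", 10)
cat(sprintf("%d/%d units pass the 10-correct-trials-per-condition rule\n",
            length(keep_units), nrow(sess$units)))

tens <- bin_spikes(sess, align = "is", window = c(-0.5, 1),
                   width_ms = 150, step_ms = 15, units = keep_units)
keep_tr <- sess$trials$correct & !sess$trials$correction
tens$counts <- tens$counts[, keep_tr, , drop = FALSE]
labels <- sess$trials$association_id[keep_tr]

om <- omega_timecourse(tens, labels, reps = 50,
                       seed = stream_seed(seed, "omega"))
cls <- truth$class[match(keep_units, truth$unit_id)]
pop <- data.frame(
  bin_center_ms = 1000 * om$centers_s,
  omega_bw = colMeans(om$omega[cls == "BW", , drop = FALSE], na.rm = TRUE),
  omega_nw = colMeans(om$omega[cls == "NW", , drop = FALSE], na.rm = TRUE)
)
write.csv(pop, "results/omega_timecourse.csv", row.names = FALSE)

null <- build_null(list(tens, labels), mode = "label_shuffle",
                   iterations = 500,
                   stat_fn = function(t, l) {
                     colMeans(omega_timecourse(t, l, reps = 1,
                                               seed = 2)$omega,
                              na.rm = TRUE)
                   }, seed = stream_seed(seed, "omega-null"))
lat <- onset_latency(colMeans(om$omega, na.rm = TRUE), om$centers_s,
                     null, level = 99.9)
cat(sprintf("population selectivity onset: %.1f ms after IS onset\n",
            1000 * lat))

ep <- epoch_selective_cells(sess, "association_id", units = keep_units,
                            n_shuffle = 500,
                            seed = stream_seed(seed, "epoch"))
cat(sprintf("selective cells: early %.1f%%, late %.1f%%\n",
            ep$percentages[["early"]], ep$percentages[["late"]]))

fm <- firing_metrics(sess, min_trials = 30)
rates <- setNames(fm$rate, fm$unit_id)[keep_units]
matched <- tryCatch(rate_match_population(rates, 2.5, 0.2),
                    error = function(e) NULL)
tf <- task_related_filter(sess)

jsonlite::write_json(
  list(onset_latency_ms = 1000 * lat,
       pct_selective = as.list(ep$percentages),
       n_rate_match_removed = if (is.null(matched)) NA else
         matched$n_removed,
       n_task_related = sum(tf$task_related),
       n_low_rate = sum(tf$low_rate)),
  "results/selectivity.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/omega_timecourse.csv, results/selectivity.json\n")
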