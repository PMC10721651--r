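# popcoding

Static vs dynamic population coding analysis for prefrontal single-unit
recordings during associative learning.

## The problem

During stimulus-response (S-R) learning, prefrontal neurons carry task
information either through a **static** population code - the same
activity pattern holds through the delay, so a decoder trained at one
time generalizes to others - or a **dynamic** one, where coding is
strong at every moment but the pattern keeps changing. Whether these
schemes segregate by cell type (broad-spiking putative pyramidal cells,
BW, vs narrow-spiking putative interneurons, NW) and change with
learning is the scientific question this pipeline addresses. The
package implements every analysis stage for three-alternative tasks
(three stimuli, three saccade targets, an instruction-stimulus (IS)
period of 1-2 s) and a synthetic-session generator with known ground
truth, so the whole chain is testable without recorded data.

## What is implemented

* **Behavior** - moving-average learning curves
  `p_k = (2w+1)^{-1} sum n_i`, the binomial learning-completion trial
  (5-trial window, p_null = 0.45, all 5 correct), learning /
  post-learning block splits, across-session performance curves.
* **Cell types** - waveform cleaning and amplitude QC, cubic
  interpolation 25 -> 2.5 us, trough-to-peak durations, Hartigan dip
  test (uniform and Gaussian-calibrated Monte-Carlo references),
  1- vs 2-component Gaussian mixture with AIC/BIC, posterior-odds (>= 10)
  cutoffs giving BW / NW / NC labels, and baseline firing rate, Fano
  factor and ISI CV.
* **Selectivity** - omega-squared explained variance
  `(SSB - df*MSE)/(SST + MSE)` per unit and 150 ms/15 ms time bin with
  50 balanced trial subsamples, onset latencies vs label-shuffle nulls,
  epoch-wise selective-cell percentages, rate-matching / task-related /
  low-rate control filters.
* **Decoding** - cross-temporal decoding over 50 ms IS bins with a
  maximum-correlation classifier, 10-fold CV over pseudotrials,
  train-set z-scoring, unit/trial resampling runs, within-unit
  label-shuffle null stacks.
* **Stability** - static classification of off-diagonal bin pairs (no
  significant accuracy drop from either on-diagonal bin, above-chance,
  Bonferroni-gated diagonal), the smoothed stability index per
  on-diagonal bin, and its unit-resampling bootstrap SD.
* **Statistics** - max-sum cluster-based permutation tests with three
  null constructions (label shuffle, cell-type shuffle, 46-mix /
  1035-difference mixed-population null) and 2x2 chi-square proportion
  comparisons.

## Worked example

```r
library(popcoding)

cfg <- synth_config(n_units_bw = 35, n_units_nw = 15,
                    selectivity_profile = "static", effect_size = 3,
                    n_trials = 120, task = "novelmap", seed = 7)
s <- generate_session(cfg)$session

# learning point from the behavioral sequence
estimate_learning_trial(as.integer(s$trials$correct))
#> [1] 18

# decode the S-R association across the IS period
tens <- bin_spikes(s, align = "is", window = c(0, 1),
                   width_ms = 50, step_ms = 50)
keep <- s$trials$correct
tens$counts <- tens$counts[, keep, , drop = FALSE]
dec <- cross_temporal_decode(tens, s$trials$association_id[keep],
                             folds = 10, runs = 10, shuffles = 500,
                             seed = 2)
round(range(diag(dec$ctd)), 2)
#> [1] 0.63 0.86

st <- classify_static_bins(dec)
si <- stability_index(st)
mean(si$smoothed[11:20])   # late-IS stability, 1 = fully static
#> [1] 0.805
```

The generated learner reaches criterion at trial 18 (its change
point is trial 16; the estimator lags by up to one 5-trial window).
The diagonal accuracies (0.63-0.86 against chance 1/3) say the
association is decodable in every 50 ms bin; a late-IS stability index
of 0.8 says most off-diagonal bin pairs generalize - the static coding
scheme the generator was configured to produce. A `"switching"` profile
run the same way yields a low index with intact diagonal decoding: a
dynamic code.

The numbered scripts under `analysis/` run the full workflow on
simulated sessions (01 simulate, 02 learning curves, 03 cell types,
04 selectivity, 05 decoding and stability) and write their tables and
JSON summaries under `results/`.

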