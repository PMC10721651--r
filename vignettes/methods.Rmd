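---
title: "Static and dynamic population coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic population coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`popcoding` implements an analysis pipeline for extracellular single-unit
recordings from three-alternative associative tasks: behavioral
learning-point estimation, waveform-based classification of putative
pyramidal (broad-spiking, BW) and interneuron (narrow-spiking, NW)
cells, omega-squared selectivity time courses, cross-temporal population
decoding, a static/dynamic stability index, and cluster-based
permutation statistics. This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken
where the methods literature leaves choices open.

## Task and data model

Each trial presents a fixation spot for 1 s, then an instruction
stimulus (IS) for 1, 1.5 or 2 s drawn pseudorandomly; IS offset is the
go signal for a saccade to one of three targets (top/right/left). The
analysis epoch for all population analyses is the first second of the IS
period. A session is one recording day of one task: a trial table with
three-level condition labels (stimulus, response target, or
stimulus-response association), per-unit spike times relative to
fixation onset, mean waveforms sampled at 25 microseconds with per-sample
SD, and unit metadata. `bin_spikes()` produces units x trials x bins
count/rate tensors with half-open bins `[t0 + b*step, t0 + b*step + width)`;
only fully contained bins exist (no partial edge bins), so a
`[-0.5, 1)` s window at 150 ms width and 15 ms step yields
`floor((1500 - 150)/15) + 1 = 91` bins. Bins extending beyond a trial's
IS duration are flagged invalid rather than zero-filled. Bin timestamps
are bin centers; reported latencies inherit that convention (the
alternative, left edges, would shift every latency by half a width and
is not otherwise distinguishable).

## Synthetic sessions as the test bed

No recorded data ship with the package; every downstream stage is
exercised on sessions from `generate_session()`, which has full ground
truth. The generator emulates:

* **Waveforms.** Trough-to-peak (t2p) durations are drawn from a
  two-Gaussian mixture (defaults 0.42 +/- 0.07 ms for BW, 0.18 +/- 0.04 ms
  for NW, mirroring the bimodal geometry of macaque prefrontal
  recordings). Traces are difference-of-Gaussians bumps - a small
  positive pre-peak, a unit-amplitude trough, and a positive post-peak
  placed t2p later - with lobe widths proportional to t2p so the
  post-trough maximum lands within one raw sample of the drawn value.
  The waveform shape itself is synthetic by design: only the extrema
  geometry and amplitude ratios matter to the classification pipeline.
  A contamination fraction can inject axon-like shapes that violate the
  amplitude QC rules.
* **Spiking.** A renewal process with piecewise-constant rate per trial
  epoch, simulated by time rescaling. The default is homogeneous
  Poisson; a gamma-renewal shape parameter generates sub-Poisson
  (regular) firing so that Fano/CV validation covers both regimes.
  Baseline rates are gamma-distributed across units around class means
  (2.1 sp/s BW, 5.1 sp/s NW - the class asymmetry reported for
  prefrontal baseline firing).
* **Selectivity profiles.** `static` multiplies the preferred
  condition's IS rate by `effect_size` for the whole IS period;
  `transient` does so only within a sub-window; `switching` swaps the
  preferred condition at a configurable time. These are the canonical
  single-unit substrates of static and dynamic population codes:
  sustained selectivity supports cross-temporal generalization, while
  short-lived or preference-switching selectivity supports on-diagonal
  decoding without generalization.
* **Behavior.** A Bernoulli step learner: correct with `p_pre` (default
  1/3, chance) before `change_trial` (default 16) and `p_post` (default
  0.95) after. Strategy sessions instead draw near-ceiling performance
  and build the repeat/change trial structure (repeat trials keep the
  previous response; change trials shift), so no fixed
  stimulus-response mapping exists by design.

All randomness flows from one master seed split into named streams
(`stream_seed()`), so each stage is reproducible in isolation. What the
generator does **not** emulate: slow drifts and nonstationarity in
firing, correlated trial-to-trial noise across units, eye-movement
artifacts, overlapping cell-type property distributions (bursting
pyramidal cells with narrow waveforms and the like), and
reward-magnitude effects. Passing tests therefore demonstrate that the
pipeline recovers known structure under clean renewal-process
assumptions - not that it would resolve every ambiguity of real
recordings.

## Learning-point estimation

The moving-average performance at trial *k* is the mean correctness over
the fully contained window of `2w + 1` trials centered on *k* (default
`w = 2`, a 5-trial window). The learning-completion trial is the center
of the earliest window whose correct count reaches the binomial
criterion: the smallest *m* with `P(Binom(2w+1, p_null) >= m) < 0.05`
under the null probability of correct `p_null = 0.45`, which for the
5-trial window requires all five trials correct. Sessions are expected
to have at least 42 trials when replicating the selection rule
(`min_trials` guard). Learning is estimated on the concatenated
correctness over all associations in session order by default - one
learning point per session - because the block split that follows is
session-level; a per-association estimate can be obtained by subsetting
trials before calling the estimator. Trial *k* belongs to the learning
block; the post-learning block starts at `k + 1`. On step learners the
estimate lags the true change point by up to one window (median lag 0-4
trials), since the first all-correct window can only begin after the
change.

## Cell-type classification

Mean waveforms are cleaned (spike waveforms exceeding 3 SD from the
initial average at any sample are removed and the mean recomputed),
QC-filtered (drop if the main trough is smaller than the following peak,
or the preceding peak exceeds the trough by more than 20% - axon-like
shapes), cubic-spline interpolated from 25 to 2.5 microseconds,
normalized to trough = -1, and measured from the main trough to the
following peak.

Bimodality of the t2p distribution is tested with a Hartigan dip
statistic implemented from its definition: the minimal sup-norm distance
between the empirical distribution function and the class of unimodal
distribution functions, computed via greatest-convex-minorant /
least-concave-majorant deviations over all candidate modes, with the
midpoint ECDF convention `F_i = (i - 1/2)/n` splitting the step
ambiguity evenly. Two Monte-Carlo p-values are reported: the classical
uniform-null reference (`p_original`), and a calibrated variant whose
null is a moment-matched Gaussian (`p_calibrated`). The Gaussian
reference is more sensitive because Gaussian samples have smaller dips
than uniform ones, so the uniform-null test is conservative against
near-Gaussian unimodal alternatives; both are Monte-Carlo tests and are
calibrated by construction against their own reference. Constant input
returns p = 1 by convention.

One- and two-component Gaussian mixtures are fitted by maximum
likelihood (the two-component fit via `mclust`, unequal variances; the
one-component fit in closed form), compared by AIC and BIC. The narrow
component is by definition the one with the smaller mean. Two cutoffs
are searched on a 1 microsecond grid - finer than the interpolated
sampling, so no label depends on the grid: the largest duration where
the posterior odds for narrow exceed 10, and the smallest where the odds
for broad exceed 10. Durations at or below the first cutoff are NW, at
or above the second BW, and strictly between the two NC (unclassified);
boundary values are classified, not NC. Firing metrics in the baseline
epoch use sample statistics (n - 1): rate, Fano factor (across-trial
count variance over mean), and ISI CV pooled within trials only (trials
are non-contiguous recordings, so across-trial gaps are not ISIs). Both
are ~1 for Poisson firing; note the CV estimator is biased low when the
epoch contains only a few ISIs per trial (mean ISI comparable to the
window), which matters below ~5 sp/s in a 1-2 s window - validation
therefore uses rates where the windowed bias is negligible.

## Omega-squared selectivity

Selectivity is the bias-adjusted fraction of firing-rate variance
explained by the three-level task variable,

  omega^2 = (SS_between - df * MSE) / (SS_total + MSE),  df = G - 1,

with MSE the within-group mean square, i.e. the within-group sum of
squares divided by `N - G`. A strict mode that uses the raw within-group
sum of squares as "MSE" exists for comparison (`mse_mode = "printed"`),
but it is dimensionally inconsistent as a variance fraction and the
pipeline never uses it. Raw values may be mildly negative by
construction; they are retained in averages (clipping would bias
population means upward) and clipped only for display. To remove the
condition-count bias, each unit's trials are balanced by subsampling
every condition without replacement to the smallest condition count; the
estimate is the mean over 50 such draws, and one draw is reused across
all time bins within a repetition (redrawing per bin would only add
Monte-Carlo noise with no change in expectation). Time courses use
150 ms bins stepped by 15 ms.

Population significance at each bin is assessed against nulls built by
permuting condition labels independently within each unit (1000
iterations), thresholded at the pointwise 99.9th percentile; onset
latency is the first significant bin center at or after IS onset.
Per-cell latencies use each cell's own label-shuffle null at the same
percentile - the per-cell criterion is not pinned down by the
literature, and a cell-level permutation threshold is the direct analog
of the population rule. Epoch-wise selectivity recomputes balanced
omega-squared on single epoch-wide bins (early 50-450 ms, late
500-900 ms) against 1000 label shuffles at p < 0.05. The task-related
control keeps units whose per-trial baseline rates differ from either IS
phase (early 50-400 ms, late 400-900 ms) by Kruskal-Wallis at p < 0.05;
the two analyses intentionally keep their distinct epoch boundaries
(450/500 vs 400/400) as separate named defaults. A caveat documented
here because it surprises on synthetic data: the Kruskal-Wallis compares
rate samples from windows of different lengths, and for discrete
low-rate Poisson counts those distributions differ under stationarity
(different discreteness and zero mass), so the filter retains many
stationary units; it is a coarse screen, not a calibrated test. The
rate-matching control removes the highest-rate unit iteratively until
the population mean is at or below 2.5 + 0.2 sp/s; the low-rate flag
marks units at or below 0.5 Hz over the session.

## Cross-temporal decoding

Spike counts in 50 ms bins tiling the 1 s IS period (20 bins) feed a
maximum-correlation-coefficient classifier. Per cross-validation fold,
each unit is z-scored with the mean and SD of its training pseudotrials
pooled over all conditions - computed from the training bin and applied
to both training and test data, so no test information leaks; each
condition's template is its mean training vector; the predicted
condition maximizes the Pearson correlation between the test vector and
the templates, with exact ties broken uniformly at random and zero-SD
units dropped from the fold. Pseudo-populations are built by sampling 10
trials per condition independently per unit (units need not share
sessions); the 10 pseudotrials are split 9/1 in a leave-one-out over the
10 slots. The whole procedure repeats over runs (50 by default),
resampling units (to the number-matched size) and trials each run, and
accuracies are averaged over folds then runs; training and testing at
every ordered bin pair yields the cross-temporal accuracy matrix (CTD),
chance = 1/3. The null stack shuffles condition labels independently
within each unit - once per iteration, reused across all bin pairs, so
the null preserves each unit's temporal autocorrelation - and decodes
identically (one run per iteration); one null stack serves all runs of a
configuration. Min-max normalization of the matrix is display-only; all
statistics run on raw accuracies.

A practical note on resolution: each accuracy cell rests on 30 test
predictions per run (10 folds x 3 conditions), so single-run accuracies
are granular at 1/30 and the extreme cell of a 20 x 20 signal-free
matrix deviates from chance by ~0.09 at 10 runs; at the procedure's own
50 runs with units resampled per run the extreme deviation is ~0.04.
Chance-calibration checks therefore run the full 50 runs. The null
percentile used by the on-diagonal significance gate (p < 0.0025
Bonferroni over 20 bins) likewise needs more than 400 null iterations to
be attainable at all; scaled-down runs use 420-500 iterations, the full
analysis 1000.

## Static bins and the stability index

An off-diagonal bin pair (tp1, tp2) is **static** when all of the
following hold: the accuracy drops from both corresponding on-diagonal
bins, `CTD(tp1,tp1) - CTD(tp1,tp2)` and `CTD(tp2,tp2) - CTD(tp1,tp2)`,
are each below the 99.9th percentile of the same differences computed
across the null stack; the off-diagonal accuracy exceeds the 99.9th
percentile of its own null accuracies; and both on-diagonal bins are
significant at the Bonferroni-corrected permutation level (0.05/20 =
0.0025). The schematic raw inequality "CTD(tp1,tp2) not less than
CTD(tp1,tp1)" is deliberately implemented as this statistical version: a
raw inequality would classify almost nothing static under sampling
noise. The drop and above-chance criteria are applied pointwise at the
99.9th percentile rather than through the 1-D cluster machinery -
scattered 2-D off-diagonal points have no natural contiguity, so
cluster-forming is reserved for 1-D series. On-diagonal entries are 0 by
convention.

The stability index at on-diagonal bin *k* is the proportion of static
flags over row *k* and column *k* (diagonal excluded); the smoothed
index averages the raw index over bins k-1..k+1, truncated at the edges
(no padding - padding would invent data). Bins whose on-diagonal
accuracy is not significant are masked *after* smoothing (masking first
would let a single non-significant bin distort its neighbors' smoothed
values); two-population comparisons additionally restrict to bins
significant for both populations. Index variability comes from
repeating the full decode + null + index computation over unit
resamples with replacement (bootstrap, 50 resamples in the full
analysis) and taking per-bin SDs.

## Cluster-based permutation statistics

Three null constructions serve the time-resolved tests: (1) condition
labels permuted within unit, for against-chance tests of omega-squared
and decoding; (2) unit reassignment between two populations of the
original sizes, for BW-vs-NW differences in per-unit statistics; (3) the
mixed-population null for stability-index comparisons, where each full
index evaluation is expensive: the pooled units are sampled (without
replacement) into a size-matched pseudo-population 46 times, each mix's
stability index is computed, and all 46 x 45 / 2 = 1035 pairwise
differences per time point form the null. The 46 is a published compute
compromise and is configurable; reduced-scale checks use 10 mixes (45
differences), whose minimal attainable cluster p-value is 1/46, so
those checks test at p < 0.05 rather than the full-scale p < 0.001.
Candidate clusters are maximal runs of contiguous bins exceeding the
per-bin 99.9th percentile of the null; the cluster mass is the sum of
the observed statistic over the run; null iterations are clustered
against the same thresholds and their maximal masses form the reference;
a cluster's p-value is the fraction of null max masses at or above its
mass (add-one correction), significant at p < 0.001 by default.
Two-population stability comparisons are run one-sided in each direction
separately, since the directional claims are asymmetric. Proportions of
selective or static cells are compared with the standard 2 x 2
chi-square without continuity correction.

## Numerical choices and degenerate inputs

* Percentiles use R's default empirical quantile (type 7) throughout.
* Permutation p-values use the add-one convention `(b + 1)/(m + 1)`.
* `omega_squared` returns 0 when the total variance is zero; the dip
  test returns p = 1 for constant input; `normalize_ctm` maps a constant
  matrix to 0.5 with a warning; correlation against a constant test
  vector is undefined and yields a seeded uniform prediction.
* Mixture EM failures and equal-mean degenerate fits raise errors rather
  than returning silently wrong cutoffs.
* The static-bin rule refuses null stacks with fewer than 100
  iterations; percentile thresholds are meaningless below that.

## Problem sizes used in the shipped checks

The test suite and acceptance script exercise the pipeline at sizes
chosen to estimate each quantity stably on a single CPU: 1300 units for
the waveform mixture (the scale at which the dip test and AIC/BIC
comparison operate), 200 signal-free units for omega-squared
calibration (1000-iteration nulls), 100-200 units / 50 runs / 100
shuffles for decoding chance calibration, 100-unit populations with 500
null iterations for stability recovery, 10 mixes for the reduced
mixed-population null, 200 simulated learners for the change-point
estimator, and 1000 signal-free series for family-wise error
calibration. The full-scale defaults (50 runs, 1000 shuffles, 46 mixes,
50 bootstrap resamples) remain the package defaults.

## Known limitations

* The generator's clean renewal assumptions make recovery easier than on
  real data; absolute percentages (of selective cells, of static bins)
  are generator-dependent and should not be read as predictions for any
  recorded dataset.
* The dip statistic uses a discrete-mode convention that differs from
  the classical tabulated implementation by O(1/n); since p-values are
  Monte-Carlo against the same statistic, tests remain calibrated, but
  dip *values* should not be compared against published tables at small
  n.
* The task-related Kruskal-Wallis screen is not calibrated for discrete
  low-rate spike counts across unequal windows (see above).
* Decoding treats units as conditionally independent given the
  condition (pseudo-populations); noise correlations are neither
  simulated nor exploited.
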