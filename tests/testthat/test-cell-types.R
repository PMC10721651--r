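test_that("spike-waveform cleaning rejects multi-point 3 SD outliers", {
  base <- sin(seq(0, 2 * pi, length.out = 40))
  spikes <- matrix(base, 50, 40, byrow = TRUE)
  same <- clean_waveform(rbind(base, base, base))
  expect_identical(same$n_rejected, 0L)
  expect_equal(same$mean, base, ignore_attr = TRUE)
  # one spike with a single-sample artifact: its deviation in SDs is
  # (n-1)/sqrt(n) ~ 6.9, every other spike sits at 1/sqrt(n)
  spikes2 <- spikes
  spikes2[7, 20] <- spikes2[7, 20] + 1
  cl <- clean_waveform(spikes2)
  expect_identical(cl$n_rejected, 1L)
  expect_equal(cl$mean[20], base[20])
  # every spike carries its own artifact at a distinct sample: each one
  # deviates by (n-1)/sqrt(n) ~ 3.2 SD there, so all are rejected
  all_bad <- matrix(base, 12, 40, byrow = TRUE)
  for (i in 1:12) all_bad[i, i] <- all_bad[i, i] + 100
  expect_error(clean_waveform(all_bad), "all spike")
})

test_that("rejection fraction matches the analytic exceedance rate", {
  set.seed(12)
  n_pts <- 30
  spikes <- matrix(rnorm(2000 * n_pts), 2000)
  frac <- clean_waveform(spikes)$fraction_rejected
  p_one <- 2 * pnorm(-3)
  p_any <- 1 - (1 - p_one)^n_pts
  se <- sqrt(p_any * (1 - p_any) / 2000)
  expect_lt(abs(frac - p_any), 4 * se + 0.01)
})

test_that("QC drops axon-like amplitude configurations", {
  mk <- function(pre, trough, post) {
    c(0, pre, 0, trough, 0, post, 0)
  }
  expect_true(qc_exclude(mk(0.2, -1, 0.4))$keep)
  bad1 <- qc_exclude(mk(0.2, -1, 1.1))
  expect_false(bad1$keep)
  expect_match(bad1$reason, "trough smaller")
  bad2 <- qc_exclude(mk(1.21, -1, 0.4))
  expect_false(bad2$keep)
  expect_match(bad2$reason, "pre-peak")
  expect_true(qc_exclude(mk(1.19, -1, 0.4))$keep)
  mono <- qc_exclude(c(0, -1)) # nothing after the trough
  expect_false(mono$keep)
  expect_match(mono$reason, "no peak")
})

test_that("trough-to-peak is measured on the interpolated grid", {
  # raw extrema 16 samples apart at 25 us -> 0.400 ms
  t_ms <- (0:71) * 0.025
  v <- popcoding:::waveform_shape(t_ms, 0.4)
  m <- measure_trough_to_peak(v)
  expect_lt(abs(m$t2p_ms - 0.4), 0.0025 + 1e-9)
  expect_equal(min(m$interpolated), -1)
  expect_false(m$at_end)
  # interpolation factor 10: indices map to 2.5 us steps
  expect_equal(m$t2p_ms, (m$peak_idx - m$trough_idx) * 0.0025)
  # time reversal measures a different (pre-trough) distance
  rev_m <- measure_trough_to_peak(rev(v))
  expect_gt(abs(rev_m$t2p_ms - m$t2p_ms), 0.01)
})

test_that("dip test separates unimodal from bimodal samples", {
  expect_identical(test_bimodality(rep(1, 10))$p_original, 1)
  set.seed(13)
  uni <- vapply(1:5, function(i) {
    test_bimodality(rnorm(400), n_mc = 400, seed = i)$p_original
  }, numeric(1))
  expect_gte(mean(uni > 0.05), 0.8)
  bim <- c(rnorm(200, 0.18, 0.04), rnorm(200, 0.42, 0.07))
  bt <- test_bimodality(bim, n_mc = 400, seed = 3)
  expect_lt(bt$p_original, 0.02)
  expect_lt(bt$p_calibrated, 0.02)
  expect_gt(bt$dip, 0)
})

test_that("mixture cutoffs recover well-separated classes", {
  set.seed(14)
  t2p <- c(rnorm(300, 0.15, 0.02), rnorm(700, 0.45, 0.03))
  truth <- rep(c("NW", "BW"), c(300, 700))
  fit <- fit_mixture_and_cutoffs(t2p)
  expect_true(fit$prefers_two)
  expect_gt(fit$cutoff_low, 0.15)
  expect_lt(fit$cutoff_high, 0.45)
  lab <- assign_cell_types(t2p, fit)
  non_nc <- lab != "NC"
  expect_gte(mean(lab[non_nc] == truth[non_nc]), 0.95)
  # single-Gaussian data: both criteria prefer one component
  g1 <- rnorm(800, 0.3, 0.05)
  f1 <- fit_mixture_and_cutoffs(g1)
  expect_false(f1$prefers_two)
})

test_that("cutoffs are symmetric for symmetric equal-weight components", {
  set.seed(15)
  t2p <- c(rnorm(1000, 0.2, 0.03), rnorm(1000, 0.5, 0.03))
  fit <- fit_mixture_and_cutoffs(t2p)
  mid <- (fit$mean_narrow + fit$mean_broad) / 2
  expect_lt(abs((fit$cutoff_low + fit$cutoff_high) / 2 - mid), 0.01)
})

test_that("label assignment conventions and invariances hold", {
  cuts <- list(cutoff_low = 0.25, cutoff_high = 0.35)
  expect_identical(assign_cell_types(0.25, cuts), "NW")
  expect_identical(assign_cell_types(0.35, cuts), "BW")
  expect_identical(assign_cell_types(0.30, cuts), "NC")
  x <- c(0.1, 0.26, 0.33, 0.5)
  shifted <- assign_cell_types(x + 0.2,
                               list(cutoff_low = 0.45, cutoff_high = 0.55))
  expect_identical(shifted, assign_cell_types(x, cuts))
})

test_that("firing metrics match hand computation and conventions", {
  # counts 2, 4, 3, 3 in the fixation second
  spk <- list(c(0.1, 0.2), c(0.1, 0.3, 0.5, 0.7),
              c(0.2, 0.4, 0.6), c(0.25, 0.5, 0.75))
  s <- manual_session(spk)
  fm <- firing_metrics(s, epoch = c(0, 1), min_trials = 4)
  expect_equal(fm$rate, 3)
  expect_equal(fm$fano, (2 / 3) / 3) # sample variance (n - 1) over mean
  expect_error(firing_metrics(s, min_trials = 30), NA) # NA row, no error
  expect_true(is.na(firing_metrics(s, min_trials = 30)$fano))
  # perfectly regular ISIs in trial 4 repeated alone -> CV = 0
  s2 <- manual_session(rep(list(c(0.2, 0.4, 0.6, 0.8)), 30))
  fm2 <- firing_metrics(s2, min_trials = 30)
  expect_equal(fm2$cv, 0)
  expect_equal(fm2$fano, 0)
  # no ISIs anywhere -> CV masked
  s3 <- manual_session(rep(list(0.5), 30))
  expect_true(is.na(firing_metrics(s3)$cv))
})
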