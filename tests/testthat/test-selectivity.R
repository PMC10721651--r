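test_that("omega-squared matches hand computation and conventions", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- rep(1:3, each = 2)
  expect_equal(omega_squared(x, g), 15 / 18)
  # strict printed-form MSE (raw within-group SS) for comparison
  expect_equal(omega_squared(x, g, mse_mode = "printed"),
               (16 - 2 * 1.5) / (17.5 + 1.5))
  expect_identical(omega_squared(rep(2, 9), rep(1:3, 3)), 0)
  # non-3-level groupings are allowed but warned about
  expect_warning(o2 <- omega_squared(1:4, c(1, 1, 2, 2)), "group")
  expect_true(is.finite(o2))
  expect_error(omega_squared(1:4, factor(c(1, 1, 2, 2), levels = 1:3)),
               "empty group")
})

test_that("omega-squared equals a brute-force ANOVA-based oracle", {
  set.seed(21)
  for (i in 1:200) {
    g <- factor(rep(1:3, times = sample(3:8, 3, replace = TRUE)))
    x <- rnorm(length(g), mean = as.integer(g) * runif(1, 0, 2))
    fit <- stats::anova(stats::lm(x ~ g))
    ssb <- fit$`Sum Sq`[1]
    sse <- fit$`Sum Sq`[2]
    mse <- fit$`Mean Sq`[2]
    oracle <- (ssb - fit$Df[1] * mse) / (ssb + sse + mse)
    expect_lt(abs(omega_squared(x, g) - oracle), 1e-12)
  }
})

test_that("omega-squared is affine invariant and permutation centered", {
  set.seed(22)
  x <- rnorm(30)
  g <- rep(1:3, 10)
  expect_equal(omega_squared(x + 5, g), omega_squared(x, g))
  expect_equal(omega_squared(x * -2.5, g), omega_squared(x, g))
  perms <- vapply(1:10000, function(i) omega_squared(x, sample(g)),
                  numeric(1))
  expect_lt(abs(mean(perms)), 0.01)
})

test_that("balanced subsampling is a no-op for equal condition counts", {
  gs <- make_session("static", effect = 3, n_bw = 4, n_nw = 0,
                     n_trials = 30, seed = 23,
                     learner = list(p_pre = 1, p_post = 1,
                                    change_trial = 1))
  d <- is_tensor(gs$session, window = c(0, 1), width_ms = 150,
                 step_ms = 150)
  # equal counts by construction of the label cycle
  labs <- rep(1:3, 10)
  d$tensor$counts <- d$tensor$counts[, 1:30, , drop = FALSE]
  om1 <- omega_timecourse(d$tensor, labs, reps = 1, seed = 1)
  om50 <- omega_timecourse(d$tensor, labs, reps = 20, seed = 2)
  expect_equal(om1$omega, om50$omega)
})

test_that("population omega tracks generator effect size monotonically", {
  pop_omega <- function(eff, seed) {
    gs <- make_session("static", effect = eff, n_bw = 12, n_nw = 4,
                       n_trials = 90, seed = seed)
    d <- is_tensor(gs$session, window = c(0, 1), width_ms = 150,
                   step_ms = 15)
    om <- omega_timecourse(d$tensor, d$labels, reps = 10, seed = 1)
    mean(colMeans(om$omega, na.rm = TRUE))
  }
  o1 <- pop_omega(1, 24)
  o2 <- pop_omega(2, 24)
  o3 <- pop_omega(4, 24)
  expect_lt(o1, o2)
  expect_lt(o2, o3)
  expect_lt(abs(o1), 0.02) # null effect stays near zero
})

test_that("onset latency tracks where selectivity begins", {
  lat_of <- function(start, seed) {
    gs <- make_session("transient", effect = 4, n_bw = 16, n_nw = 6,
                       n_trials = 120, seed = seed,
                       transient_window = c(start, 1))
    d <- is_tensor(gs$session, window = c(-0.5, 1), width_ms = 150,
                   step_ms = 15)
    om <- omega_timecourse(d$tensor, d$labels, reps = 5, seed = 1)
    null <- build_null(list(d$tensor, d$labels), mode = "label_shuffle",
                       iterations = 150,
                       stat_fn = function(t, l) {
                         colMeans(omega_timecourse(t, l, reps = 1,
                                                   seed = 2)$omega,
                                  na.rm = TRUE)
                       }, seed = 3)
    onset_latency(colMeans(om$omega, na.rm = TRUE), om$centers_s, null,
                  level = 99)
  }
  l_early <- lat_of(0.2, 25)
  l_late <- lat_of(0.5, 25)
  expect_lt(l_early, l_late)
  # bin-width tolerance: onset within [start - width, start + width]
  expect_gte(l_early, 0.2 - 0.15)
  expect_lte(l_early, 0.2 + 0.15)
  # no-signal population never crosses the null
  gs0 <- make_session("none", n_bw = 10, n_nw = 4, n_trials = 90,
                      seed = 26)
  d0 <- is_tensor(gs0$session, window = c(-0.5, 1), width_ms = 150,
                  step_ms = 15)
  om0 <- omega_timecourse(d0$tensor, d0$labels, reps = 5, seed = 1)
  null0 <- build_null(list(d0$tensor, d0$labels), mode = "label_shuffle",
                      iterations = 150,
                      stat_fn = function(t, l) {
                        colMeans(omega_timecourse(t, l, reps = 1,
                                                  seed = 2)$omega,
                                 na.rm = TRUE)
                      }, seed = 3)
  expect_true(is.na(onset_latency(colMeans(om0$omega, na.rm = TRUE),
                                  om0$centers_s, null0, level = 99.9)))
})

test_that("epoch selectivity separates early-only modulation", {
  gs <- make_session("transient", effect = 3, n_bw = 24, n_nw = 8,
                     n_trials = 100, seed = 27,
                     transient_window = c(0, 0.5))
  ep <- epoch_selective_cells(gs$session, "association_id",
                              n_shuffle = 200, seed = 5)
  expect_gt(ep$percentages[["early"]], ep$percentages[["late"]])
  # all-zero rates: nothing can be flagged
  s0 <- gs$session
  s0$spikes <- s0$spikes[0, ]
  ep0 <- epoch_selective_cells(s0, "association_id", n_shuffle = 100,
                               seed = 5)
  expect_equal(unname(ep0$percentages), c(0, 0))
})

test_that("rate matching removes highest-rate units greedily", {
  r <- c(a = 1, b = 2, c = 3, d = 10)
  m <- rate_match_population(r, target_mean = 2.5, tol = 0.2)
  expect_identical(m$n_removed, 1L)
  expect_setequal(m$units, c("a", "b", "c"))
  expect_equal(m$mean_rate, 2)
  same <- rate_match_population(c(x = 2, y = 3), target_mean = 2.5)
  expect_identical(same$n_removed, 0L)
  expect_error(rate_match_population(c(x = 9, y = 10), target_mean = 1),
               "closest achievable")
  # removal count non-increasing in the target mean
  set.seed(28)
  rates <- setNames(rexp(40, 1 / 3), paste0("u", 1:40))
  removed <- vapply(c(1.5, 2, 2.5, 3),
                    function(t) rate_match_population(rates, t)$n_removed,
                    integer(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("task-related filter keeps modulated units and flags low rates", {
  gs <- make_session("static", effect = 4, n_bw = 12, n_nw = 0,
                     rate_bw = 10, n_trials = 100, seed = 29,
                     rate_dispersion = 1e6)
  tf <- task_related_filter(gs$session)
  expect_gte(mean(tf$task_related), 0.9)
  expect_false(any(tf$low_rate))
  # a 0.4 Hz unit trips the low-rate flag
  lo <- make_session("none", n_bw = 2, n_nw = 0, rate_bw = 0.4,
                     n_trials = 80, seed = 30, rate_dispersion = 1e6)
  tf2 <- task_related_filter(lo$session)
  expect_true(all(tf2$low_rate))
})
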