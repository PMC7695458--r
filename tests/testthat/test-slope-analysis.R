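test_that("Gaussian smoothing turns a delta into a 20 ms bump and keeps flats flat", {
  x <- numeric(1001)
  x[501] <- 1000   # one spike in a 1 ms bin, as a rate impulse
  sm <- rewardDDM:::gauss_smooth(x, sigma = 0.020, dt = 0.001)
  expect_equal(which.max(sm), 501)
  # matches the Gaussian kernel shape with sd 20 ms
  tt <- (seq_along(x) - 501) * 0.001
  expect_lt(max(abs(sm - 1000 * 0.001 * dnorm(tt, sd = 0.020))), 0.01)
  # flat input stays flat, including at the edges (kernel renormalisation)
  flat <- rewardDDM:::gauss_smooth(rep(5, 300), sigma = 0.020, dt = 0.001)
  expect_equal(flat, rep(5, 300), tolerance = 1e-10)
})

test_that("condition PSTHs estimate rates and truncate at the median RT", {
  tt <- quick_trials(400L, seed = 31L, coh_set = c(0.128, 0.512))
  nr <- poisson_recording(tt, rep(20, 400), seed = 6L)
  nr$preferred_choice <- "reference"
  ps <- condition_psth(nr, "motion", "all")
  for (cn in ps$conditions) {
    expect_true(all(abs(cn$rate - 20) < 6))  # 20 Hz within sampling noise
    expect_lt(max(cn$time), cn$median_rt)
    expect_gte(min(cn$time), 0)
  }
  ps2 <- condition_psth(nr, "saccade", "all")
  for (cn in ps2$conditions) expect_lte(max(cn$time), 0)
})

test_that("slope estimation is exact on linear and constant curves", {
  tt <- seq(0, 1, by = 0.001)
  st <- slope_timeseries(tt, 10 + 20 * tt)
  expect_equal(st$slope, rep(20, nrow(st)), tolerance = 1e-8)
  st0 <- slope_timeseries(tt, rep(7, length(tt)))
  expect_equal(st0$slope, rep(0, nrow(st0)), tolerance = 1e-10)
  # too-short curve: no windows
  expect_equal(nrow(slope_timeseries(tt[1:100], tt[1:100])), 0L)
})

test_that("slope estimation is unbiased on noisy ramps", {
  set.seed(41)
  tt <- seq(0, 0.4, by = 0.001)
  sl <- replicate(100, {
    noisy <- 10 + 30 * tt + rnorm(length(tt), 0, 3)
    mean(slope_timeseries(tt, noisy)$slope)
  })
  expect_lt(abs(mean(sl) - 30), 2 * sd(sl) / sqrt(100))
})

test_that("slope modulation regression is exact on noiseless condition slopes", {
  grid <- expand.grid(coherence = c(0, 0.128, 0.256, 0.512),
                      context = c(-1, 1))
  grid$slope <- 5 * grid$coherence + 1 * grid$context
  mr <- slope_modulation_regression(grid)
  expect_equal(mr$beta[mr$regressor == "coherence"], 5, tolerance = 1e-10)
  expect_equal(mr$beta[mr$regressor == "context"], 1, tolerance = 1e-10)
  expect_equal(mr$beta[mr$regressor == "interaction"], 0, tolerance = 1e-8)
  flat <- grid; flat$slope <- 4
  mf <- slope_modulation_regression(flat)
  expect_equal(mf$beta[mf$regressor != "intercept"], rep(0, 3),
               tolerance = 1e-10)
  expect_equal(mf$beta[mf$regressor == "intercept"], 4)
  one <- grid[grid$context == 1, ]
  expect_warning(slope_modulation_regression(one), "aliased")
  expect_error(slope_modulation_regression(grid[grid$coherence == 0, ]),
               "coherence levels")
})

test_that("slope modulation recovery from Poisson spike trains", {
  fx <- fixtures("monkeyA-like")
  cfg <- fx$configs[[1]]
  cfg$trials_per_block <- 100L
  tt <- generate_behavior_session(cfg)
  enc <- encoding_spec(baseline = 15, g0 = 10, g_coh = 60, g_ctx = 12,
                       ramp_tau = 0.25, burst_amp = 0)
  nr <- generate_spike_trains(tt, enc, seed = 51L)
  nr$preferred_choice <- "reference"
  ss <- slope_series(nr, "motion", "preferred")
  # in the early build-up the fitted coherence/context modulation should
  # carry the generative signs and order
  early <- ss[ss$center <= 0.25, ]
  expect_gt(mean(early$beta_coh), 0)
  expect_gt(mean(early$beta_ctx), 0)
})

test_that("peak-window selection respects latency, significance and magnitude", {
  ser <- data.frame(center = c(0.05, 0.12, 0.18, 0.24),
                    beta_coh = c(9, 4.0, 2.0, 3.0),
                    p_coh = c(0.001, 0.01, 0.20, 0.04),
                    beta_ctx = c(1, 0.8, 0.5, 0.3),
                    p_ctx = 0.5, beta_int = 0, p_int = 0.5,
                    n_conditions = 8, alignment = "motion")
  pk <- peak_window_ratio(ser)
  # the 0.05 s window is below the imposed visual latency; 0.18 s is not
  # significant; the largest significant |beta_coh| at or after 0.1 s wins
  expect_equal(pk$center, 0.12)
  expect_equal(pk$ratio, 0.8 / 4.0)
  # adding windows with non-significant coherence leaves the choice alone
  extra <- rbind(ser, transform(ser[4, ], center = 0.4, beta_coh = 50,
                                p_coh = 0.6))
  expect_equal(peak_window_ratio(extra)$center, 0.12)
  # no significant window: ineligible
  none <- ser; none$p_coh <- 0.5
  expect_false(peak_window_ratio(none)$eligible)
})

test_that("ratio-bias correlation handles identities and degenerate input", {
  x <- c(0.1, 0.2, 0.35, 0.5)
  out <- ratio_bias_correlation(x, x)
  expect_equal(out$r, 1)
  expect_equal(out$slope, 1)
  expect_error(ratio_bias_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(out0 <- ratio_bias_correlation(rep(1, 5), x[c(1, 2, 3, 4, 1)]),
                 "zero variance")
  expect_true(is.na(out0$r))
})

test_that("slope summary tables round-trip through the source-data adapter", {
  fx <- fixtures("drift-coupled", n_sessions = 4)
  rows <- lapply(1:4, function(i) {
    tt <- generate_behavior_session(fx$configs[[i]])
    nr <- generate_spike_trains(tt, fx$encodings[[i]], seed = 60L + i)
    nr$preferred_choice <- "reference"
    slope_series(nr, "motion", "preferred")
  })
  tab <- slope_summary_table(rows)
  expect_named(tab, c("neuron_id", "alignment", "peak_window_s", "beta_coh",
                      "beta_context", "beta_interaction", "ratio",
                      "eligible"))
  tab$delta_drift <- vapply(fx$configs[1:4], function(cf)
    compute_biases(cf$params)$delta_drift, numeric(1))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  got <- read_slope_source_data(f)
  expect_equal(got$correlation$n, sum(tab$eligible))
})
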