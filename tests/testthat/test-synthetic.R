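test_that("session generator follows the block schedule and task rules", {
  cfg <- session_config(trials_per_block = 40L, n_blocks = 8L, seed = 5L)
  tt <- generate_behavior_session(cfg)
  r <- rle(tt$reward_context)
  expect_equal(r$values, rep(c(1, -1), 4))
  expect_true(all(r$lengths == 40L | attr(tt, "n_lapse") > 0))
  expect_silent(validate_trial_table(tt, check_blocks = TRUE))
  # fraction correct rises with coherence magnitude
  mag <- abs(tt$signed_coherence)
  fc <- tapply(tt$correct, mag, mean)
  expect_gt(fc[[length(fc)]], fc[[1]])
  expect_gt(fc[[length(fc)]], 0.9)
  # purely a function of (config, seed)
  expect_identical(tt, generate_behavior_session(cfg))
  expect_error(generate_behavior_session(
    session_config(coherence_set = numeric(0))), "non-empty")
})

test_that("reward sizes follow the context-choice contingency", {
  tt <- small_session()
  # large reward expected iff the choice side matches the context's large
  # side; for correct reference choices in ref-large blocks that is TRUE
  rs <- tt$choice * tt$reward_context
  i <- which(tt$choice == 1 & tt$reward_context == 1)
  expect_true(all(rs[i] == 1))
  j <- which(tt$choice == -1 & tt$reward_context == 1)
  expect_true(all(rs[j] == -1))
})

test_that("spike generator is reproducible and respects the null encoding", {
  tt <- small_session()
  spec0 <- encoding_spec(baseline = 20, context_offset = 0, g0 = 0,
                         g_coh = 0, g_ctx = 0, burst_amp = 0)
  nr <- generate_spike_trains(tt, spec0, seed = 3L)
  expect_identical(nr$spikes, generate_spike_trains(tt, spec0, seed = 3L)$spikes)
  # homogeneous Poisson: epoch regression finds nothing
  er <- epoch_regression(nr, design = "coherence")
  b <- er[er$regressor != "intercept" & !er$degenerate, ]
  expect_gt(mean(abs(b$beta) < 2 * b$se, na.rm = TRUE), 0.85)
  # empirical rate near 20 Hz
  total_time <- sum(tt$t_saccade_on_s + 0.6 - (tt$t_target_on_s - 0.4))
  expect_lt(abs(sum(lengths(nr$spikes)) / total_time - 20), 1)
  expect_error(generate_spike_trains(tt, encoding_spec(baseline = -1)),
               "baseline")
})

test_that("saccade detection applies both kinematic thresholds", {
  # stationary eye: nothing to detect
  expect_true(is.na(detect_saccade(rep(0, 1000))))
  # constant-velocity drift at 50 deg/s exceeds the velocity criterion but
  # not the acceleration criterion
  drift <- 50 * seq(0, 0.999, by = 0.001)
  expect_true(is.na(detect_saccade(drift)))
  # a saccade with a triangular velocity profile starting at 0.4 s:
  # acceleration 16000 deg/s^2 to a 400 deg/s peak (10 degree amplitude).
  # The oracle is the analytic time at which velocity crosses 40 deg/s.
  tt <- seq(0, 0.999, by = 0.001)
  vel <- pmax(0, 400 * (1 - abs(tt - 0.425) / 0.025))
  pos <- cumsum(vel) * 0.001
  onset <- detect_saccade(data.frame(time = tt, position = pos))
  t_cross <- 0.4 + 40 / 16000
  expect_lt(abs(onset - t_cross), 0.002 + 1e-9)
})

test_that("fixture presets are frozen, valid and self-describing", {
  expect_error(fixtures("nope"), "presets")
  nul <- fixtures("null")
  p <- nul$configs[[1]]$params
  expect_equal(unname(p$me_by_context), c(0, 0))
  expect_equal(unname(diff(p$z_by_context)), 0)
  enc <- nul$encodings[[1]]
  expect_equal(enc$g_ctx + enc$g_coh + enc$context_offset, 0)
  dc <- fixtures("drift-coupled")
  expect_length(dc$configs, 30L)
  for (i in c(1L, 30L)) {
    dd <- compute_biases(dc$configs[[i]]$params)$delta_drift
    expect_equal(dc$encodings[[i]]$g_ctx / dc$encodings[[i]]$g_coh, 2 * dd)
  }
  bc <- fixtures("bound-coupled")
  expect_gt(bc$configs[[1]]$z_coupling_gamma, 0)
  expect_gt(compute_biases(bc$configs[[1]]$params)$delta_bound, 0)
  for (nm in c("monkeyA-like", "monkeyC-like", "monkeyF-like")) {
    fx <- fixtures(nm)
    expect_s3_class(fx$configs[[1]], "session_config")
    expect_s3_class(fx$encodings[[1]], "encoding_spec")
  }
})

test_that("generated data round-trip through the text formats", {
  tt <- small_session()
  f <- tempfile(fileext = ".csv")
  write_trial_table(tt, f)
  back <- read_trial_table(f)
  expect_equal(back$rt_s, tt$rt_s, tolerance = 1e-12)
  expect_equal(back$signed_coherence, tt$signed_coherence)

  nr <- small_neuron()
  fs <- tempfile(fileext = ".jsonl")
  write_spike_trains(nr, fs)
  nb <- read_spike_trains(fs, tt)
  expect_equal(nb$spikes, nr$spikes, tolerance = 1e-9)
  expect_equal(nb$region, nr$region)
  expect_equal(nb$preferred_choice, nr$preferred_choice)
})

test_that("trial-table validation catches each schema violation", {
  tt <- toy_trials()
  expect_silent(validate_trial_table(tt))
  bad <- tt; bad$rt_s[2] <- bad$rt_s[2] + 0.01
  expect_error(validate_trial_table(bad), "within 1 ms")
  bad2 <- tt; bad2$reward_context[1] <- 0
  expect_error(validate_trial_table(bad2), "reward_context")
  bad3 <- tt; bad3$t_target_on_s[3] <- bad3$t_motion_on_s[3] + 0.1
  expect_error(validate_trial_table(bad3), "event times")
  expect_error(validate_trial_table(tt[, -3]), "lacks columns")
  expect_error(validate_trial_table(data.frame()), "non-empty")
  blocky <- tt; blocky$reward_context <- c(1, 1, -1, -1, 1, 1, -1, -1)
  expect_silent(validate_trial_table(blocky, check_blocks = TRUE))
})
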