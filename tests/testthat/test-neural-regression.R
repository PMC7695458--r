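test_that("epoch windows follow the stated arithmetic", {
  ev <- data.frame(t_target_on_s = 0, t_motion_on_s = 0.9,
                   t_saccade_on_s = 1.42)
  ep <- define_epochs(ev, median_rt = 0.52)
  expect_equal(unname(ep$start[1, 3]), 0.5)   # pre-motion 400 ms
  expect_equal(unname(ep$end[1, 3]), 0.9)
  expect_equal(unname(ep$start[1, 4]), 1.0)   # motion + 0.1
  expect_equal(unname(ep$end[1, 4]), 1.32)    # motion + median_rt - 0.1
  expect_equal(unname(ep$start[1, 6]), 1.32)
  expect_equal(unname(ep$end[1, 6]), 1.42)
  expect_equal(unname(ep$start[1, 8]), 1.42)
  expect_equal(unname(ep$end[1, 8]), 1.82)
  # peri-saccade window always contains the pre-saccade window
  expect_true(ep$start[1, 7] <= ep$start[1, 6] && ep$end[1, 7] >= ep$end[1, 6])
  expect_false(any(ep$degenerate))
})

test_that("fast trials flag variable epochs as degenerate, never dropped", {
  ev <- data.frame(t_target_on_s = 0, t_motion_on_s = 0.9,
                   t_saccade_on_s = 1.05)  # RT 0.15 < 0.2 s
  ep <- define_epochs(ev, median_rt = 0.15)
  expect_true(ep$degenerate[1, 4])
  expect_true(ep$degenerate[1, 5])  # epoch 5 end (S - 0.1) < start (M + 0.1)
  expect_equal(dim(ep$start), c(1L, 8L))
})

test_that("indicator coding matches the task conventions", {
  tt <- toy_trials()
  X <- regression_design(tt, "coherence")
  # reference choice in a reference-large block: all indicators +1
  i <- which(tt$choice == 1 & tt$reward_context == 1)[1]
  expect_equal(X$choice[i], 1)
  expect_equal(X$reward_context[i], 1)
  expect_equal(X$reward_size[i], 1)
  # other choice in a reference-large block expects the small reward
  j <- which(tt$choice == -1 & tt$reward_context == 1)[1]
  expect_equal(X$reward_size[j], -1)
  # coherence magnitude is routed to the chosen side's regressor
  expect_equal(X$coh_contra[i], abs(tt$signed_coherence[i]))
  expect_equal(X$coh_ipsi[i], 0)
  expect_equal(X$rewcoh_contra[i], X$coh_contra[i] * X$reward_size[i])
})

test_that("design matrices are reproducible and RT regressors centred", {
  tt <- quick_trials(200L, seed = 5L)
  X1 <- regression_design(tt, "rt")
  X2 <- regression_design(tt, "rt")
  expect_identical(X1, X2)
  # golden values: mean-subtracted RTs are zero-mean within context x choice
  for (rc in c(1, -1)) for (ch in c(1, -1)) {
    sel <- tt$reward_context == rc & tt$choice == ch
    rtc <- (X1$rt_contra + X1$rt_ipsi)[sel]
    expect_equal(mean(rtc), 0, tolerance = 1e-12)
  }
})

test_that("epoch regression recovers injected coefficients and nulls", {
  tt <- quick_trials(600L, seed = 7L)
  nr0 <- poisson_recording(tt, rate_per_trial = rep(20, 600), seed = 2L)
  er <- epoch_regression(nr0, design = "coherence")
  expect_s3_class(er, "epoch_regression")
  expect_equal(nrow(er), 8L * 8L)  # 8 epochs x (intercept + 7 regressors)
  # constant-rate neuron: coefficients consistent with zero
  b <- er[er$regressor != "intercept" & er$epoch == 3, ]
  expect_true(all(abs(b$beta) < 3.5 * b$se))

  # inject a known linear model into epoch-3 counts via the rate
  X <- regression_design(tt, "coherence")
  lam <- 8 + 2 * X$choice + 1.5 * X$reward_context + 4 * X$coh_contra
  set.seed(42)
  counts <- rpois(600, lam)
  fit <- rewardDDM:::fit_count_regression(counts, X)
  for (term in c("choice", "reward_context", "coh_contra")) {
    row <- fit[fit$regressor == term, ]
    truth <- c(choice = 2, reward_context = 1.5, coh_contra = 4)[[term]]
    expect_lt(abs(row$beta - truth), 3.5 * row$se)
  }
})

test_that("constant counts yield exactly zero slopes", {
  tt <- quick_trials(200L, seed = 9L)
  X <- regression_design(tt, "coherence")
  fit <- rewardDDM:::fit_count_regression(rep(7, 200), X)
  b <- fit$beta[fit$regressor != "intercept"]
  expect_equal(unname(b), rep(0, length(b)), tolerance = 1e-10)
})

test_that("aliased design columns are dropped with a warning", {
  tt <- quick_trials(200L, seed = 10L, coh_set = 0.256)
  tt$choice <- sign(tt$signed_coherence)   # single magnitude, both choices
  X <- regression_design(tt, "coherence")
  set.seed(1)
  expect_warning(rewardDDM:::fit_count_regression(rpois(200, 10), X),
                 "aliased")
})

test_that("running regression windows march in steps and honour trial minima", {
  nr <- small_neuron()
  rr <- running_regression(nr, "motion", "rt", span = c(-0.2, 0.6))
  centers <- sort(unique(rr$center))
  expect_equal(centers, seq(-0.2, 0.6, by = 0.01), tolerance = 1e-9)
  expect_true(all(!rr$excluded))
  # with only 8 correct trials, every window is short of the 10-trial floor
  few <- nr$trials[nr$trials$correct == 1, ][1:8, ]
  nr_few <- neuron_recording("few", nr$spikes[match(few$trial_index,
                                                    nr$trials$trial_index)],
                             few)
  expect_message(
    rr_few <- running_regression(nr_few, "motion", "rt", span = c(0, 0.1)),
    "no window")
  expect_true(all(rr_few$excluded))
  expect_true(all(is.na(rr_few$beta)))
})

test_that("running regression localises an injected choice step", {
  tt <- quick_trials(500L, seed = 12L)
  set.seed(13)
  # rate steps up by 12 sp/s for reference choices from +0.2 s after motion
  spikes <- lapply(seq_len(500L), function(i) {
    t0 <- tt$t_target_on_s[i] - 0.4
    t1 <- tt$t_saccade_on_s[i] + 0.6
    step_at <- tt$t_motion_on_s[i] + 0.2
    base <- sort(runif(rpois(1, 15 * (t1 - t0)), t0, t1))
    extra <- if (tt$choice[i] == 1)
      sort(runif(rpois(1, 12 * (t1 - step_at)), step_at, t1)) else numeric(0)
    sort(c(base, extra))
  })
  nr <- neuron_recording("step", spikes, tt)
  rr <- running_regression(nr, "motion", "rt", span = c(-0.1, 0.5))
  ch <- rr[rr$regressor == "choice" & !rr$excluded, ]
  ch <- ch[order(ch$center), ]
  # onset = first window opening a sustained run of significant positive
  # choice coefficients (a lone spurious window does not count)
  sig <- ch$p < 0.05 & ch$beta > 0
  sustained <- sig & c(sig[-1], FALSE) & c(sig[-(1:2)], FALSE, FALSE)
  onset <- ch$center[which(sustained)[1]]
  expect_lt(abs(onset - 0.2), 0.08 + 1e-9)  # half window + step
})

test_that("shuffle null follows the add-one rank rule and segment logic", {
  tt <- quick_trials(300L, seed = 14L)
  set.seed(15)
  counts <- rpois(300, 10)
  pool <- rep(rep(c(1, -1), each = 40), length.out = 2000)
  out <- serial_correlation_null(counts, tt, pool, design = "coherence",
                                 n_null = 100L, seed = 3L)
  expect_length(out$null_betas, 100L)
  k <- sum(abs(out$null_betas) >= abs(out$observed_beta))
  expect_equal(out$p_adjusted, (1 + k) / 101)
  # an observed effect exceeding every null draw gets the minimal p; the
  # pool's block length differs from the session's so no null segment can
  # align perfectly with the true context sequence
  pool28 <- rep(rep(c(1, -1), each = 28), length.out = 2000)
  out2 <- serial_correlation_null(counts + 5 * (tt$reward_context == 1),
                                  tt, pool28, n_null = 100L, seed = 3L)
  expect_equal(out2$p_adjusted, 1 / 101)
  expect_error(serial_correlation_null(counts, tt, pool[1:350]),
               "pool shorter")
})

test_that("classification applies the inclusion and selectivity rules", {
  tt <- quick_trials(600L, seed = 16L)
  # low-rate neuron (about 3 Hz peak) is excluded
  nr_low <- poisson_recording(tt, rep(3, 600), seed = 4L)
  er_low <- epoch_regression(nr_low, design = "rt")
  cls_low <- classify_neurons(er_low, nr_low)
  expect_false(cls_low$included)
  expect_lt(cls_low$peak_rate, 5)

  # rule application on constructed coefficient tables
  base <- expand.grid(epoch = 1:8,
                      regressor = c("intercept", "choice", "reward_context"))
  base$beta <- 0; base$se <- 1; base$p <- 0.9
  base$design <- "rt"
  sel <- base
  sel$beta[sel$epoch == 5 & sel$regressor == "choice"] <- 2.1
  sel$p[sel$epoch == 5 & sel$regressor == "choice"] <- 0.01
  sel$beta[sel$epoch == 6 & sel$regressor == "choice"] <- 1.8
  sel$p[sel$epoch == 6 & sel$regressor == "choice"] <- 0.02
  nr_ok <- poisson_recording(tt, rep(25, 600), seed = 5L)
  cls <- classify_neurons(sel, nr_ok)
  expect_true(cls$choice_selective)
  expect_equal(cls$preferred_choice, "reference")
  # significant but sign-inconsistent modulation is not selectivity
  flip <- sel
  flip$beta[flip$epoch == 6 & flip$regressor == "choice"] <- -1.8
  cls2 <- classify_neurons(flip, nr_ok)
  expect_false(cls2$choice_selective)
})

test_that("population fractions pool regressors with the matching chance level", {
  set.seed(21)
  # synthetic per-neuron results: two pooled regressors, all null
  mk <- function(id, region) {
    do.call(rbind, lapply(1:8, function(e) data.frame(
      epoch = e, regressor = c("coh_contra", "coh_ipsi", "choice"),
      beta = rnorm(3), se = 1, p = runif(3), neuron_id = id,
      region = region)))
  }
  res <- do.call(rbind, lapply(1:60, function(i)
    mk(paste0("n", i), if (i <= 30) "FEF" else "caudate")))
  pf <- population_fractions(res)
  pooled <- pf[pf$category == "coh_either", ]
  expect_equal(unique(pooled$chance), 1 - 0.95^2)
  single <- pf[pf$category == "choice", ]
  expect_equal(unique(single$chance), 0.05)
  # all-null population: fractions near chance, no Bonferroni hits
  expect_false(any(pf$sig_vs_chance, na.rm = TRUE))
  expect_lt(abs(mean(single$fraction) - 0.05), 0.03)
  expect_lt(abs(mean(pooled$fraction) - (1 - 0.95^2)), 0.04)
})
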