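test_that("bound profile follows the logistic collapse geometry", {
  p <- ddm_params(k = 6, z_by_context = 0.5, a = 2, beta_alpha = 0,
                  beta_d = 0)
  b <- bound_profile(c(0, 0.5, 3), p)
  expect_equal(b$upper, rep(0.5, 3))   # B = a/2 constant when collapse is off
  expect_equal(b$lower, rep(-0.5, 3))

  p2 <- ddm_params(k = 6, z_by_context = 0.7, a = 2, beta_alpha = 5,
                   beta_d = 5)
  b2 <- bound_profile(1, p2)           # B(1) = 2 / (1 + e^0) = 1
  expect_equal(b2$upper, 0.3)
  expect_equal(b2$lower, -0.7)

  # z = 0.5 means equal bound heights at every time
  p3 <- ddm_params(k = 6, z_by_context = 0.5, a = 1.7, beta_alpha = 3,
                   beta_d = 4)
  tt <- seq(0, 4, by = 0.25)
  b3 <- bound_profile(tt, p3)
  expect_equal(abs(b3$upper), abs(b3$lower))

  expect_error(bound_profile(-0.1, p), "t must be")
})

test_that("parameter container enforces its invariants", {
  expect_error(ddm_params(k = -1), "k must be")
  expect_error(ddm_params(k = 1, a = 0), "a must be")
  expect_error(ddm_params(k = 1, z_by_context = c(0.5, 1.2)), "z_by_context")
  expect_error(ddm_params(k = 1, t0 = -0.1), "t0")
  p <- ddm_params(k = 2, me_by_context = c("ref-small" = -0.1,
                                           "ref-large" = 0.2))
  expect_equal(p$me_by_context[["ref-large"]], 0.2)  # reordered by name
  # YAML round trip
  f <- tempfile(fileext = ".yaml")
  write_ddm_params(p, f)
  expect_equal(read_ddm_params(f), p)
})

test_that("solver conserves probability and absorbs almost all mass", {
  g <- first_passage_grid(ddm_params(k = 6, me_by_context = 0.03,
                                     z_by_context = 0.45, a = 1.8),
                          coherence = 0.128, dt = 0.001, dx = 0.025)
  pu <- cumsum(g$upper) * 0.001
  pl <- cumsum(g$lower) * 0.001
  expect_lt(max(abs(pu + pl + g$residual - 1)), 1e-6)
  expect_gte(pu[length(pu)] + pl[length(pl)], 0.999)
  expect_true(all(g$upper >= 0) && all(g$lower >= 0))
})

test_that("solver is symmetric for unbiased parameters and under reflection", {
  p <- ddm_params(k = 6, me_by_context = 0, z_by_context = 0.5, a = 1.8)
  g <- first_passage_grid(p, coherence = 0, dt = 0.001, dx = 0.02)
  expect_lt(max(abs(g$upper - g$lower)), 1e-4)

  # negating coherence and me while reflecting z swaps the two bounds
  pa <- ddm_params(k = 6, me_by_context = c(0.2, -0.2),
                   z_by_context = c(0.35, 0.65), a = 1.8)
  pb <- ddm_params(k = 6, me_by_context = c(-0.2, 0.2),
                   z_by_context = c(0.65, 0.35), a = 1.8)
  ga <- first_passage_grid(pa, coherence = 0.128, context = "ref-large",
                           dt = 0.001, dx = 0.02)
  gb <- first_passage_grid(pb, coherence = -0.128, context = "ref-large",
                           dt = 0.001, dx = 0.02)
  n <- min(length(ga$time), length(gb$time))
  expect_lt(max(abs(ga$upper[1:n] - gb$lower[1:n])), 1e-6)
  expect_lt(max(abs(ga$lower[1:n] - gb$upper[1:n])), 1e-6)
})

test_that("solver refuses too-coarse state grids", {
  p <- ddm_params(k = 6)
  expect_error(first_passage_grid(p, 0, dt = 0.001, dx = 0.05), "coarse")
  expect_error(first_passage_grid(p, 0, dt = 0, dx = 0.02), "must be > 0")
})

test_that("choice probabilities converge under grid refinement", {
  p <- ddm_params(k = 6, me_by_context = c(0.05, -0.03),
                  z_by_context = c(0.48, 0.55), a = 1.8)
  pu <- vapply(c(0.002, 0.001), function(dtv) {
    g <- first_passage_grid(p, 0.064, dt = dtv, dx = 0.4 * sqrt(dtv))
    sum(g$upper) * dtv
  }, numeric(1))
  expect_lt(abs(pu[1] - pu[2]), 1e-3)
})

test_that("simulator matches its contracts", {
  p <- ddm_params(k = 6, me_by_context = 0, z_by_context = 0.5, a = 1.8)
  expect_error(simulate_trials(p, 0, dt = 0.01), "dt must lie")
  s <- simulate_trials(p, 0, n_per_coherence = 10000L, seed = 5L)
  expect_true(all(s$rt > p$t0 | s$lapse))
  # unbiased zero-coherence trials split 50/50 within binomial error
  ph <- mean(s$choice == "upper")
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 10000))
  # a positive drift offset in the large-reward context biases choices up
  pb <- ddm_params(k = 6, me_by_context = c(0.1, -0.1), z_by_context = 0.5,
                   a = 1.8)
  sb <- simulate_trials(pb, 0, "ref-large", n_per_coherence = 4000L,
                        seed = 6L)
  expect_gt(mean(sb$choice == "upper"), 0.5)
  # reproducibility: same seed, byte-identical outcome
  expect_identical(simulate_trials(p, c(0, 0.128), n_per_coherence = 50L,
                                   seed = 9L),
                   simulate_trials(p, c(0, 0.128), n_per_coherence = 50L,
                                   seed = 9L))
})

test_that("solver and simulator agree on choice fractions and RT quantiles", {
  p <- ddm_params(k = 6, me_by_context = c(0.05, -0.03),
                  z_by_context = c(0.45, 0.55), a = 1.8)
  for (ctx in c("ref-large", "ref-small")) {
    n <- 20000L
    s <- simulate_trials(p, 0.128, ctx, n_per_coherence = n, dt = 0.001,
                         seed = 31L)
    g <- first_passage_grid(p, 0.128, ctx, dt = 0.001, dx = 0.02)
    pu_g <- sum(g$upper) * 0.001
    pu_s <- mean(s$choice == "upper")
    expect_lt(abs(pu_g - pu_s), 3 * sqrt(pu_g * (1 - pu_g) / n))
    # median decision time of upper-bound trials
    med_g <- rewardDDM:::fpt_quantiles(g, 0.5, "upper")
    dts <- s$rt[s$choice == "upper"] - p$t0
    med_s <- median(dts)
    dens <- approx(g$time, g$upper / pu_g, xout = med_g)$y
    se_med <- sqrt(0.25 / length(dts)) / dens
    expect_lt(abs(med_g - med_s), 3 * se_med)
  }
})

test_that("predicted psychometric and chronometric curves behave", {
  p <- ddm_params(k = 6, me_by_context = 0, z_by_context = 0.5, a = 1.8,
                  t0 = 0.3)
  coh <- c(-0.512, -0.128, 0, 0.128, 0.512)
  tab <- predict_choice_rt(p, coh)
  expect_true(all(diff(tab$p_upper) > 0))              # monotone in drift
  expect_equal(tab$p_upper + rev(tab$p_upper), rep(1, 5), tolerance = 1e-6)
  expect_true(all(tab$mean_rt_upper > p$t0))
  expect_error(predict_choice_rt(p, numeric(0)), "non-empty")
  # against Monte Carlo
  s <- simulate_trials(p, 0.256, n_per_coherence = 20000L, seed = 17L)
  t2 <- predict_choice_rt(p, 0.256)
  pu <- mean(s$choice == "upper")
  expect_lt(abs(t2$p_upper - pu), 3 * sqrt(pu * (1 - pu) / 20000))
  expect_lt(abs(t2$mean_rt_upper - mean(s$rt[s$choice == "upper"])),
            3 * sd(s$rt[s$choice == "upper"]) / sqrt(sum(s$choice == "upper")))
})
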