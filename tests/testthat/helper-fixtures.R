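# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small biased session (320 trials, default monkey-like parameters)
small_session <- function() {
  cached("small_session", {
    generate_behavior_session(session_config(seed = 11L))
  })
}

# a spiking neuron on the small session with moderate encoding
small_neuron <- function() {
  cached("small_neuron", {
    nr <- generate_spike_trains(
      small_session(),
      encoding_spec(baseline = 20, context_offset = 3, g0 = 8, g_coh = 60,
                    g_ctx = 6, burst_amp = 40),
      seed = 21L)
    nr$preferred_choice <- "reference"
    nr
  })
}

# hand-built trial table with exact, easily checked values
toy_trials <- function(n = 8L) {
  rt <- seq(0.45, 0.45 + 0.05 * (n - 1), by = 0.05)
  tg <- seq(0, by = 3, length.out = n)
  mo <- tg + 0.8
  data.frame(
    session_id = "toy", trial_index = seq_len(n),
    reward_context = rep(c(1, -1), each = n / 2),
    signed_coherence = rep(c(0.256, -0.128, 0.512, -0.512), length.out = n),
    choice = rep(c(1, -1, 1, -1), length.out = n),
    correct = rep(1, n), rt_s = rt,
    t_target_on_s = tg, t_motion_on_s = mo, t_saccade_on_s = mo + rt)
}

# direct logistic choice generator: the oracle for fit_logistic
sample_logistic_session <- function(n, slope0, slope_rew, bias0, bias_rew,
                                    coh_set = c(0, 0.032, 0.064, 0.128,
                                                0.256, 0.512),
                                    seed = 1L) {
  set.seed(seed)
  rc <- rep(c(1, -1), each = ceiling(n / 80) * 40)[seq_len(n)]
  coh <- sample(coh_set, n, replace = TRUE) * sample(c(1, -1), n, TRUE)
  slope <- slope0 + slope_rew * rc
  bias <- bias0 + bias_rew * rc
  pr <- plogis(slope * (coh + bias))
  ch <- ifelse(runif(n) < pr, 1, -1)
  rt <- runif(n, 0.4, 0.9)
  tg <- seq(0, by = 3, length.out = n)
  data.frame(session_id = "logit", trial_index = seq_len(n),
             reward_context = rc, signed_coherence = coh, choice = ch,
             correct = as.integer(sign(coh) == ch), rt_s = rt,
             t_target_on_s = tg, t_motion_on_s = tg + 0.8,
             t_saccade_on_s = tg + 0.8 + rt)
}

# quick synthetic trial table without the DDM simulator (for regression
# designs): blocked contexts, random coherences, correct trials only
quick_trials <- function(n = 400L, block = 40L, seed = 1L,
                         coh_set = c(0, 0.064, 0.128, 0.256, 0.512)) {
  set.seed(seed)
  rc <- rep(rep(c(1, -1), length.out = ceiling(n / block)),
            each = block)[seq_len(n)]
  mag <- sample(coh_set, n, replace = TRUE)
  dirn <- sample(c(1, -1), n, TRUE)
  coh <- mag * dirn
  ch <- ifelse(mag == 0, sample(c(1, -1), n, TRUE), dirn)
  rt <- exp(rnorm(n, log(0.55), 0.2))
  tg <- seq(0, by = 3, length.out = n)
  data.frame(session_id = "quick", trial_index = seq_len(n),
             reward_context = rc, signed_coherence = coh, choice = ch,
             correct = rep(1L, n), rt_s = rt, t_target_on_s = tg,
             t_motion_on_s = tg + 0.8, t_saccade_on_s = tg + 0.8 + rt)
}

# Poisson spike trains with a constant rate per trial (vectorised)
poisson_recording <- function(trials, rate_per_trial, seed = 1L,
                              neuron_id = "pois", region = "FEF") {
  set.seed(seed)
  spikes <- lapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$t_target_on_s[i] - 0.4
    t1 <- trials$t_saccade_on_s[i] + 0.6
    k <- rpois(1, rate_per_trial[i] * (t1 - t0))
    sort(runif(k, t0, t1))
  })
  neuron_recording(neuron_id, spikes, trials, region = region)
}
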