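#' Session configuration for the synthetic task generator
#'
#' Describes one session of the reward-biased motion-discrimination task:
#' block-wise alternating reward contexts, the per-session coherence set, the
#' ground-truth collapsing-bound DDM parameters that generate choices and RTs,
#' and the inter-event timing distributions.
#'
#' @param coherence_set unsigned coherence magnitudes used in the session.
#' @param trials_per_block trials per reward-context block.
#' @param n_blocks number of blocks; contexts alternate block-wise.
#' @param params ground-truth [ddm_params()].
#' @param first_context +1 (`ref-large`) or -1 (`ref-small`) for block 1.
#' @param target_motion_delay length-2 range (s) of the uniform target-onset
#'   to motion-onset delay.
#' @param inter_trial interval (s) between one trial's saccade and the next
#'   trial's target onset.
#' @param z_coupling_gamma trial-wise bound-bias modulation: on each trial
#'   the context-specific `z` deviation from 0.5 is scaled by
#'   `(1 + gamma * u)` with latent `u ~ N(0, 1)` shared with the spike
#'   generator (0 = no trial-wise fluctuation).
#' @param session_id label.
#' @param seed integer seed; the generated session is a pure function of the
#'   configuration and this seed.
#' @return object of class `session_config`.
#' @export
session_config <- function(coherence_set = c(0, 0.032, 0.064, 0.128, 0.256, 0.512),
                           trials_per_block = 40L, n_blocks = 8L,
                           params = ddm_params(k = 6,
                                               me_by_context = c(0.03, -0.03),
                                               z_by_context = c(0.48, 0.52),
                                               a = 1.8, beta_alpha = 3,
                                               beta_d = 5, t0 = 0.3),
                           first_context = 1L,
                           target_motion_delay = c(0.5, 1.0),
                           inter_trial = 1.0,
                           z_coupling_gamma = 0,
                           session_id = "synthetic-session",
                           seed = 1L) {
  if (length(coherence_set) == 0L) stop("coherence_set must be non-empty")
  stopifnot(inherits(params, "ddm_params"),
            first_context %in% c(1L, -1L),
            length(target_motion_delay) == 2L)
  structure(list(coherence_set = coherence_set,
                 trials_per_block = as.integer(trials_per_block),
                 n_blocks = as.integer(n_blocks), params = params,
                 first_context = as.integer(first_context),
                 target_motion_delay = target_motion_delay,
                 inter_trial = inter_trial,
                 z_coupling_gamma = z_coupling_gamma,
                 session_id = session_id, seed = as.integer(seed)),
            class = "session_config")
}

#' Encoding model for synthetic spike trains
#'
#' Generative parameters for an inhomogeneous-Poisson neuron whose rate is
#' modulated by reward context, choice, coherence and RT in the same ways the
#' regression designs probe: a baseline with a reward-context offset
#' (preferred-choice frame), a linear firing-rate ramp from motion onset plus
#' a visual latency whose slope follows
#' `slope = g0 + g_coh * coh + g_ctx * I_context (+ g_int * coh * I_context)`,
#' and a Gaussian peri-saccadic burst. The instantaneous rate is clamped at 0.
#'
#' @param baseline baseline rate (spikes/s).
#' @param context_offset signed baseline offset (spikes/s) applied as
#'   `context_offset * I_context` with `I_context = +1` when the neuron's
#'   preferred choice is paired with the large reward.
#' @param latency visual latency before the ramp starts (s).
#' @param g0,g_coh,g_ctx,g_int ramp-slope law (spikes/s^2); coherence enters
#'   as unsigned magnitude.
#' @param ramp_tau saturation time constant (s) of the build-up: the
#'   instantaneous ramp slope decays as `exp(-(t - onset) / ramp_tau)`, so
#'   the rate rises toward `slope * ramp_tau` above baseline; `Inf` gives a
#'   linear ramp. Saturation leaves the context:coherence slope-modulation
#'   ratio invariant across windows while concentrating the coherence
#'   modulation early after motion onset.
#' @param null_choice_slope ramp slope on trials with the non-preferred
#'   choice (spikes/s^2), replacing the slope law.
#' @param rt_coupling additive slope term (spikes/s^2 per s) times the
#'   trial's mean-subtracted RT.
#' @param burst_amp,burst_sd peri-saccadic Gaussian burst amplitude
#'   (spikes/s) and width (s); non-preferred-choice trials get
#'   `burst_null_frac` of the amplitude.
#' @param burst_null_frac fraction of `burst_amp` for non-preferred choices.
#' @param mod_gain coupling of the baseline context offset to the session's
#'   latent trial-wise modulation `u`: the offset is scaled by
#'   `(1 + mod_gain * u)`; pairs with `z_coupling_gamma` in
#'   [session_config()] for bound-coupling studies.
#' @param preferred which choice drives the neuron (`"reference"` maps the
#'   preferred-context indicator onto `reward_context`, `"other"` onto its
#'   negative).
#' @return object of class `encoding_spec`.
#' @export
encoding_spec <- function(baseline = 20, context_offset = 0, latency = 0.1,
                          g0 = 5, g_coh = 30, g_ctx = 0, g_int = 0,
                          ramp_tau = Inf,
                          null_choice_slope = 0, rt_coupling = 0,
                          burst_amp = 40, burst_sd = 0.02,
                          burst_null_frac = 0.2, mod_gain = 0,
                          preferred = "reference") {
  if (baseline < 0) stop("baseline rate must be >= 0")
  vals <- c(baseline, context_offset, latency, g0, g_coh, g_ctx, g_int,
            null_choice_slope, rt_coupling, burst_amp, burst_sd,
            burst_null_frac, mod_gain)
  if (any(!is.finite(vals))) stop("all encoding parameters must be finite")
  if (!(ramp_tau > 0)) stop("ramp_tau must be positive (Inf for linear)")
  structure(list(baseline = baseline, context_offset = context_offset,
                 latency = latency, g0 = g0, g_coh = g_coh, g_ctx = g_ctx,
                 g_int = g_int, ramp_tau = ramp_tau,
                 null_choice_slope = null_choice_slope,
                 rt_coupling = rt_coupling, burst_amp = burst_amp,
                 burst_sd = burst_sd, burst_null_frac = burst_null_frac,
                 mod_gain = mod_gain,
                 preferred = match.arg(preferred, c("reference", "other"))),
            class = "encoding_spec")
}

#' Generate a synthetic behavioural session
#'
#' Builds a trial table from a [session_config()]: reward contexts alternate
#' in blocks, signed coherences are sampled uniformly from the coherence set
#' crossed with the two directions, choices and RTs come from the
#' collapsing-bound DDM simulator, correctness follows sign agreement between
#' coherence and choice (0%-coherence trials are rewarded by a fair coin),
#' and event times are drawn from the configured timing distributions.
#' Fully reproducible given the config (which includes the seed). The
#' returned table carries an extra `latent_mod` column (the per-trial latent
#' modulation `u` used for trial-wise bound coupling) and an `n_lapse`
#' attribute counting simulated trials not absorbed by the 10 s horizon
#' (excluded from the table).
#'
#' @param config a [session_config()].
#' @return a validated trial table (data.frame).
#' @export
generate_behavior_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  p <- config$params
  n <- config$trials_per_block * config$n_blocks
  set.seed(config$seed)

  block <- rep(seq_len(config$n_blocks), each = config$trials_per_block)
  context <- config$first_context * (-1L)^(block - 1L)
  mag <- sample(config$coherence_set, n, replace = TRUE)
  dirn <- sample(c(1, -1), n, replace = TRUE)
  coh <- mag * dirn
  u <- rnorm(n)

  ctx_lab <- context_label(context)
  me <- p$me_by_context[ctx_lab]
  z0 <- p$z_by_context[ctx_lab]
  z_trial <- 0.5 + (z0 - 0.5) * (1 + config$z_coupling_gamma * u)
  z_trial <- pmin(pmax(z_trial, 0.02), 0.98)
  drift <- p$k * (coh + me)

  sim <- cpp_sim_trials(drift, z_trial, p$a, p$beta_alpha, p$beta_d,
                        dt = 0.001, horizon = 10,
                        seed = as.integer(config$seed %% 1000000L + 7L))
  lapse <- sim$choice == 0L
  choice <- sim$choice
  rt <- sim$decision_time + p$t0

  correct <- ifelse(coh == 0, rbinom(n, 1, 0.5),
                    as.integer(sign(coh) == choice))
  delay <- runif(n, config$target_motion_delay[1], config$target_motion_delay[2])
  keep <- !lapse
  nk <- sum(keep)
  t_target <- cumsum(c(0.5, (config$inter_trial + delay[keep] + rt[keep])[-nk]))
  t_motion <- t_target + delay[keep]
  t_sacc <- t_motion + rt[keep]

  out <- data.frame(
    session_id = config$session_id,
    trial_index = seq_len(nk),
    reward_context = context[keep],
    signed_coherence = coh[keep],
    choice = choice[keep],
    correct = correct[keep],
    rt_s = rt[keep],
    t_target_on_s = t_target,
    t_motion_on_s = t_motion,
    t_saccade_on_s = t_sacc,
    latent_mod = u[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_lapse") <- sum(lapse)
  attr(out, "config") <- config
  validate_trial_table(out, check_blocks = FALSE)
}

#' Generate Poisson spike trains for a session
#'
#' Inhomogeneous-Poisson spikes on a 1 ms grid from the [encoding_spec()]
#' rate model, over the span `[target onset - 0.4 s, saccade onset + 0.6 s]`
#' of each trial. The generative parameters are stored in the returned
#' recording's `ground_truth` for recovery tests.
#'
#' @param trials a session trial table (from [generate_behavior_session()] or
#'   read from disk; a `latent_mod` column is used if present).
#' @param spec an [encoding_spec()].
#' @param seed integer seed.
#' @param neuron_id,region,monkey metadata for the recording.
#' @return a [neuron_recording()].
#' @export
generate_spike_trains <- function(trials, spec, seed = 1L,
                                  neuron_id = "syn-1", region = "FEF",
                                  monkey = "synthetic") {
  stopifnot(inherits(spec, "encoding_spec"))
  trials <- validate_trial_table(trials)
  set.seed(as.integer(seed))
  n <- nrow(trials)
  u <- if ("latent_mod" %in% names(trials)) trials$latent_mod else rep(0, n)
  sgn <- if (spec$preferred == "reference") 1 else -1
  i_ctx <- sgn * trials$reward_context          # +1: preferred paired w/ large
  pref_choice_code <- sgn                        # trial choice matching preference
  mean_rt <- mean(trials$rt_s)
  bin <- 0.001

  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    t0i <- trials$t_target_on_s[i] - 0.4
    t1i <- trials$t_saccade_on_s[i] + 0.6
    tt <- seq(t0i, t1i, by = bin)
    rate <- rep(spec$baseline + spec$context_offset * i_ctx[i] *
                  (1 + spec$mod_gain * u[i]), length(tt))
    ramp_start <- trials$t_motion_on_s[i] + spec$latency
    coh <- abs(trials$signed_coherence[i])
    if (trials$choice[i] == pref_choice_code) {
      slope <- spec$g0 + spec$g_coh * coh + spec$g_ctx * i_ctx[i] +
        spec$g_int * coh * i_ctx[i] +
        spec$rt_coupling * (trials$rt_s[i] - mean_rt)
      bamp <- spec$burst_amp
    } else {
      slope <- spec$null_choice_slope
      bamp <- spec$burst_amp * spec$burst_null_frac
    }
    ramp_level <- function(el)  # rise above baseline el seconds after onset
      if (is.finite(spec$ramp_tau))
        slope * spec$ramp_tau * (1 - exp(-el / spec$ramp_tau)) else slope * el
    ramp_on <- tt >= ramp_start & tt <= trials$t_saccade_on_s[i]
    rate[ramp_on] <- rate[ramp_on] + ramp_level(tt[ramp_on] - ramp_start)
    # hold the attained ramp level through the post-saccadic span
    if (any(ramp_on)) {
      after <- tt > trials$t_saccade_on_s[i]
      rate[after] <- rate[after] +
        ramp_level(trials$t_saccade_on_s[i] - ramp_start)
    }
    rate <- rate + bamp * exp(-0.5 * ((tt - trials$t_saccade_on_s[i]) /
                                        spec$burst_sd)^2)
    rate <- pmax(rate, 0)
    counts <- rpois(length(tt), rate * bin)
    idx <- rep.int(seq_along(tt), counts)
    spikes[[i]] <- sort(tt[idx] + runif(length(idx), 0, bin))
  }
  neuron_recording(neuron_id, spikes, trials, region = region, monkey = monkey,
                   preferred_choice = if (sgn > 0) "reference" else "other",
                   ground_truth = unclass(spec))
}

#' Detect saccade onset from an eye-position trace
#'
#' Velocity and acceleration are estimated by finite differences with a 5 ms
#' moving-average smoothing window; onset is the first sample of the
#' movement's leading edge at which velocity exceeds 40 deg/s and
#' acceleration exceeds 8000 deg/s^2.
#'
#' @param trace data.frame with columns `time` (s, uniformly sampled) and
#'   `position` (degrees), or a numeric position vector with `sample_rate`.
#' @param sample_rate Hz, used when `trace` is a bare numeric vector.
#' @param velocity_threshold deg/s.
#' @param accel_threshold deg/s^2.
#' @return onset time (s), or `NA_real_` when no sample crosses both
#'   thresholds.
#' @export
detect_saccade <- function(trace, sample_rate = 1000,
                           velocity_threshold = 40,
                           accel_threshold = 8000) {
  if (is.data.frame(trace)) {
    tt <- trace$time
    pos <- trace$position
    dtm <- median(diff(tt))
  } else {
    pos <- as.numeric(trace)
    dtm <- 1 / sample_rate
    tt <- (seq_along(pos) - 1) * dtm
  }
  if (length(pos) < 10L) stop("trace too short")
  smooth5 <- function(x) {
    k <- max(1L, round(0.005 / dtm))
    if (k %% 2L == 0L) k <- k + 1L
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  }
  vel <- smooth5(c(NA, diff(pos)) / dtm)
  acc <- smooth5(c(NA, diff(vel)) / dtm)
  hit <- which(abs(vel) > velocity_threshold & abs(acc) > accel_threshold)
  if (!length(hit)) return(NA_real_)
  tt[hit[1]]
}

#' Frozen fixture configurations
#'
#' Named presets pairing session configurations with encoding-model sets,
#' used throughout the test suite and documentation:
#' `"monkeyA-like"`, `"monkeyC-like"`, `"monkeyF-like"` — single sessions
#' with plausible log-spaced coherence sets and reward biases
#' (drift bias toward, bound bias away from, the large-reward choice);
#' `"null"` — no reward bias, no encoding modulation;
#' `"drift-coupled"` — a population of sessions whose neurons' ramp-slope
#' context:coherence ratio equals `delta_drift / 2`, the value implied when
#' the firing slope tracks the biased decision variable;
#' `"bound-coupled"` — sessions with bound biases of both signs, neurons
#' whose baseline context offsets share the bias sign, and trial-wise
#' coupling between baseline modulation and the bound bias.
#'
#' @param name preset name.
#' @param n_sessions number of sessions for the population presets.
#' @return list with `name`, `configs` (list of [session_config()]) and
#'   `encodings` (list of [encoding_spec()], one per session).
#' @export
fixtures <- function(name = c("monkeyA-like", "monkeyC-like", "monkeyF-like",
                              "null", "drift-coupled", "bound-coupled"),
                     n_sessions = NULL) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture '", name[1], "'; presets: monkeyA-like, ",
         "monkeyC-like, monkeyF-like, null, drift-coupled, bound-coupled"))
  base_params <- function(me_l = 0.03, me_s = -0.03, z_l = 0.48, z_s = 0.52)
    ddm_params(k = 6, me_by_context = c(me_l, me_s),
               z_by_context = c(z_l, z_s), a = 1.8, beta_alpha = 3,
               beta_d = 5, t0 = 0.3)
  coh_sets <- list(
    "monkeyA-like" = c(0, 0.032, 0.064, 0.128, 0.256, 0.512),
    "monkeyC-like" = c(0, 0.064, 0.128, 0.256, 0.512),
    "monkeyF-like" = c(0, 0.048, 0.096, 0.192, 0.384))

  if (name %in% names(coh_sets)) {
    cfg <- session_config(coherence_set = coh_sets[[name]],
                          params = base_params(),
                          session_id = name, seed = 100L + match(
                            name, names(coh_sets)))
    enc <- encoding_spec(baseline = 20, context_offset = 3, g_coh = 30,
                         g_ctx = 6 * 0.03, burst_amp = 40)
    return(list(name = name, configs = list(cfg), encodings = list(enc)))
  }
  if (name == "null") {
    ns <- if (is.null(n_sessions)) 20L else n_sessions
    configs <- lapply(seq_len(ns), function(i)
      session_config(params = base_params(0, 0, 0.5, 0.5),
                     session_id = sprintf("null-%02d", i), seed = 200L + i))
    encodings <- replicate(ns, encoding_spec(
      baseline = 20, context_offset = 0, g0 = 5, g_coh = 0, g_ctx = 0,
      burst_amp = 0), simplify = FALSE)
    return(list(name = name, configs = configs, encodings = encodings))
  }
  if (name == "drift-coupled") {
    ns <- if (is.null(n_sessions)) 30L else n_sessions
    dd <- seq(0.02, 0.20, length.out = ns)   # per-session drift bias
    configs <- lapply(seq_len(ns), function(i)
      session_config(coherence_set = c(0, 0.128, 0.256, 0.512),
                     params = base_params(dd[i] / 2, -dd[i] / 2, 0.5, 0.5),
                     trials_per_block = 125L, n_blocks = 24L,
                     session_id = sprintf("drift-coupled-%02d", i),
                     seed = 300L + i))
    # saturating build-up (coherence modulation of the slope peaks early;
    # the context:coherence ratio is window-invariant) with a neural context
    # gain 2x the decision-variable prediction: ratio_i = 2 * delta_drift_i.
    # No peri-saccadic burst: this preset isolates the build-up component
    # whose slope the analysis targets
    encodings <- lapply(seq_len(ns), function(i)
      encoding_spec(baseline = 10, context_offset = 0, g0 = 10, g_coh = 300,
                    g_ctx = 2 * 300 * dd[i], ramp_tau = 0.25,
                    burst_amp = 0))
    return(list(name = name, configs = configs, encodings = encodings))
  }
  # bound-coupled: every session biases the bound toward the large-reward
  # choice (delta_bound = +0.10); the neurons' baseline reward-context
  # modulation shares that sign and fluctuates trial-wise with the latent
  # modulation that also scales the bound bias
  ns <- if (is.null(n_sessions)) 24L else n_sessions
  db <- 0.10
  configs <- lapply(seq_len(ns), function(i)
    session_config(params = base_params(0.02, -0.02,
                                        0.5 + db / 2, 0.5 - db / 2),
                   z_coupling_gamma = 1.0,
                   session_id = sprintf("bound-coupled-%02d", i),
                   seed = 400L + i))
  encodings <- lapply(seq_len(ns), function(i)
    encoding_spec(baseline = 20, context_offset = 6,
                  g0 = 8, g_coh = 30, mod_gain = 1.0, burst_amp = 40))
  list(name = name, configs = configs, encodings = encodings)
}
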