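#' Collapsing bound positions at time t
#'
#' Evaluates the upper and lower absorbing bounds of the model at elapsed
#' accumulation time `t`. The total separation is
#' `B(t) = a / (1 + exp(beta_alpha * t - beta_d))`; with the accumulator
#' starting at 0, the upper bound sits at `(1 - z) * B(t)` and the lower at
#' `-z * B(t)`, so `z` is the fraction of the separation below the start point.
#'
#' @param t time since accumulation onset (s); vectorised, all `t >= 0`.
#' @param params a [ddm_params()] object.
#' @param context `"ref-large"` or `"ref-small"`.
#' @return A list with numeric vectors `upper` and `lower` (evidence units).
#' @examples
#' p <- ddm_params(k = 6, z_by_context = 0.7, a = 2, beta_alpha = 5, beta_d = 5)
#' bound_profile(1, p, "ref-large")  # B(1) = 1: upper 0.3, lower -0.7
#' @export
bound_profile <- function(t, params, context = "ref-large") {
  stopifnot(inherits(params, "ddm_params"))
  context <- match.arg(context, DDM_CONTEXTS)
  if (any(t < 0)) stop("t must be >= 0")
  B <- params$a / (1 + exp(params$beta_alpha * t - params$beta_d))
  z <- params$z_by_context[[context]]
  list(upper = (1 - z) * B, lower = -z * B)
}

#' Numerical first-passage-time distribution of the collapsing-bound DDM
#'
#' Propagates the accumulator's state density forward in time by discrete
#' Gaussian transition-kernel convolution, absorbing mass that lies beyond the
#' (collapsing) bounds at the end of every step. Returns the probability
#' density of first crossing each bound on a uniform time grid of decision
#' times (no `t0` shift; add `params$t0` to obtain response times).
#'
#' @param params a [ddm_params()] object.
#' @param coherence signed motion coherence (fraction, positive toward the
#'   upper/reference bound).
#' @param context reward context label.
#' @param dt solver time step (s).
#' @param dx state-space resolution (evidence units); must satisfy
#'   `dx <= sqrt(dt)` (one kernel standard deviation under unit diffusion).
#' @param horizon maximum decision time (s).
#' @param margin state-grid padding beyond the widest bounds (evidence units).
#' @param stop_mass propagation stops early once the un-absorbed interior
#'   mass falls below this value.
#' @return An object of class `fpt_grid`: list with `time`, `upper`, `lower`
#'   (crossing densities, 1/s), `residual` (interior mass after each step),
#'   `dt`, and the inputs.
#' @export
first_passage_grid <- function(params, coherence, context = "ref-large",
                               dt = 0.001, dx = 0.025, horizon = 10,
                               margin = 0.25, stop_mass = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  context <- match.arg(context, DDM_CONTEXTS)
  if (dt <= 0 || dx <= 0 || horizon <= 0) stop("dt, dx and horizon must be > 0")
  if (dx > sqrt(dt))
    stop(sprintf("grid too coarse: dx = %g exceeds sqrt(dt) = %g", dx, sqrt(dt)))
  drift <- params$k * (coherence + params$me_by_context[[context]])
  z <- params$z_by_context[[context]]
  out <- cpp_fpt_grid(drift, z, params$a, params$beta_alpha, params$beta_d,
                      dt, dx, horizon, margin, stop_mass)
  structure(c(out, list(dt = dt, dx = dx, coherence = coherence,
                        context = context, drift = drift)),
            class = "fpt_grid")
}

#' @export
print.fpt_grid <- function(x, ...) {
  pu <- sum(x$upper) * x$dt
  pl <- sum(x$lower) * x$dt
  cat(sprintf(
    "First-passage grid: %d steps of %g s (coh %+0.3f, %s)\n  P(upper) = %.4f, P(lower) = %.4f, residual = %.2g\n",
    length(x$time), x$dt, x$coherence, x$context, pu, pl,
    utils::tail(x$residual, 1)))
  invisible(x)
}

#' Simulate choice/RT trials from the collapsing-bound DDM
#'
#' Euler simulation `dDV = k (coh + me) dt + sqrt(dt) * eta`, `eta ~ N(0,1)`,
#' absorbed at the collapsing bounds; within-step crossings are located by
#' linear interpolation of the path against linearly interpolated bounds, and
#' the earliest interpolated crossing wins. Every trial draws from its own
#' counter-based random stream derived from `seed`, so results are
#' reproducible and independent of trial order.
#'
#' @param params a [ddm_params()] object.
#' @param coherences signed coherences; each is simulated `n_per_coherence`
#'   times.
#' @param context reward context label.
#' @param n_per_coherence trials per coherence.
#' @param dt Euler step (s), in (0, 0.005].
#' @param seed integer seed.
#' @param horizon maximum decision time (s). Trials not absorbed by the
#'   horizon are returned with `lapse = TRUE` and `rt = NA`, never dropped
#'   silently.
#' @return A data.frame with columns `coherence`, `context`, `choice`
#'   (`"upper"`/`"lower"`/`NA`), `rt` (s, includes `t0`), `lapse`.
#' @export
simulate_trials <- function(params, coherences, context = "ref-large",
                            n_per_coherence = 1L, dt = 0.001, seed = 1L,
                            horizon = 10) {
  stopifnot(inherits(params, "ddm_params"))
  context <- match.arg(context, DDM_CONTEXTS)
  if (dt <= 0 || dt > 0.005) stop("dt must lie in (0, 0.005]")
  coh <- rep(coherences, each = n_per_coherence)
  drift <- params$k * (coh + params$me_by_context[[context]])
  z <- rep(params$z_by_context[[context]], length(coh))
  sim <- cpp_sim_trials(drift, z, params$a, params$beta_alpha, params$beta_d,
                        dt, horizon, as.integer(seed))
  lapse <- sim$choice == 0L
  data.frame(
    coherence = coh,
    context = context,
    choice = ifelse(lapse, NA_character_,
                    ifelse(sim$choice > 0L, "upper", "lower")),
    rt = ifelse(lapse, NA_real_, sim$decision_time + params$t0),
    lapse = lapse,
    stringsAsFactors = FALSE
  )
}

#' Predicted choice probabilities and mean RTs
#'
#' Computes, from the numerical first-passage distribution, the probability of
#' an upper-bound (reference) choice and the mean response time conditional on
#' each choice, for a set of coherences in one reward context.
#'
#' @inheritParams first_passage_grid
#' @param coherences signed coherences (finite, non-empty).
#' @return data.frame with columns `coherence`, `p_upper`, `mean_rt_upper`,
#'   `mean_rt_lower` (RTs include `t0`).
#' @export
predict_choice_rt <- function(params, coherences, context = "ref-large",
                              dt = 0.001, dx = 0.025, horizon = 10) {
  if (length(coherences) == 0L) stop("coherences must be non-empty")
  if (any(!is.finite(coherences))) stop("coherences must be finite")
  rows <- lapply(coherences, function(co) {
    g <- first_passage_grid(params, co, context, dt = dt, dx = dx,
                            horizon = horizon)
    pu <- sum(g$upper) * dt
    pl <- sum(g$lower) * dt
    data.frame(
      coherence = co,
      p_upper = pu / (pu + pl),
      mean_rt_upper = if (pu > 0) sum(g$time * g$upper) * dt / pu + params$t0 else NA_real_,
      mean_rt_lower = if (pl > 0) sum(g$time * g$lower) * dt / pl + params$t0 else NA_real_
    )
  })
  do.call(rbind, rows)
}

# Decision-time quantiles (choice-conditional) from an fpt_grid.
fpt_quantiles <- function(grid, probs, bound = c("upper", "lower")) {
  bound <- match.arg(bound)
  dens <- grid[[bound]]
  cdf <- cumsum(dens) * grid$dt
  tot <- cdf[length(cdf)]
  if (tot <= 0) return(rep(NA_real_, length(probs)))
  approx(cdf / tot, grid$time, xout = probs, ties = "ordered")$y
}
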