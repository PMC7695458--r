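#' Fit the reward-context logistic to session choices
#'
#' Maximum-likelihood fit of the psychometric function
#' `P(reference choice) = 1 / (1 + exp(-Slope * (Coh + Bias)))` where
#' `Slope = slope0 + slope_rew * RewCont` and `Bias = bias0 + bias_rew * RewCont`,
#' with `RewCont = +1` when the reference choice is paired with the large
#' reward and `-1` otherwise. All completed trials enter the fit.
#'
#' @param trials a trial table (see [read_trial_table()]): columns
#'   `reward_context` (+1/-1), `signed_coherence`, `choice` (+1 reference /
#'   -1 other) are used.
#' @return An object of class `logistic_params`: list with `estimate`
#'   (slope0, slope_rew, bias0, bias_rew), `se`, `vcov`, `loglik`,
#'   `converged`.
#' @export
fit_logistic <- function(trials) {
  trials <- validate_trial_table(trials)
  coh <- trials$signed_coherence
  rc <- trials$reward_context
  y <- as.integer(trials$choice > 0)
  if (length(unique(coh)) < 2L) stop("need >= 2 distinct coherences")
  if (length(unique(y)) < 2L)
    stop("separation: only one choice present; logistic fit is unidentified")

  nll <- function(p) {
    slope <- p[1] + p[2] * rc
    bias <- p[3] + p[4] * rc
    eta <- slope * (coh + bias)
    -sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
  }
  # starting values from per-context GLMs: eta = b0 + b1*coh per context
  start <- tryCatch({
    per_ctx <- vapply(c(1, -1), function(r) {
      f <- glm(y[rc == r] ~ coh[rc == r], family = binomial())
      coef(f)
    }, numeric(2))
    s <- per_ctx[2, ]          # slopes per context (+1, -1)
    b <- per_ctx[1, ] / pmax(s, 1e-6)  # bias = intercept / slope
    c((s[1] + s[2]) / 2, (s[1] - s[2]) / 2, (b[1] + b[2]) / 2, (b[1] - b[2]) / 2)
  }, error = function(e) c(5, 0, 0, 0), warning = function(w) c(5, 0, 0, 0))

  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  vc <- tryCatch(solve(opt$hessian), error = function(e)
    matrix(NA_real_, 4, 4))
  nm <- c("slope0", "slope_rew", "bias0", "bias_rew")
  est <- setNames(opt$par, nm)
  if (est["slope0"] + est["slope_rew"] <= 0 ||
      est["slope0"] - est["slope_rew"] <= 0)
    warning("fitted Slope is non-positive in one context")
  structure(list(estimate = est,
                 se = setNames(sqrt(pmax(diag(vc), 0)), nm),
                 vcov = vc, loglik = -opt$value,
                 converged = opt$convergence == 0L),
            class = "logistic_params")
}

#' @export
print.logistic_params <- function(x, ...) {
  cat("Reward-context logistic fit", if (!x$converged) "(NOT converged)", "\n")
  tab <- data.frame(estimate = x$estimate, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Predicted choice probability from a logistic fit
#'
#' @param object a `logistic_params` fit.
#' @param coherence signed coherence values.
#' @param reward_context +1 / -1.
#' @param ... unused.
#' @return probability of the reference choice.
#' @export
predict.logistic_params <- function(object, coherence, reward_context, ...) {
  e <- object$estimate
  slope <- e["slope0"] + e["slope_rew"] * reward_context
  bias <- e["bias0"] + e["bias_rew"] * reward_context
  unname(plogis(slope * (coherence + bias)))
}

#' Default priors for MAP fitting of the DDM
#'
#' Weakly informative priors on the natural scale: `k` half-normal(10),
#' `a` gamma(2, 1), each `z` beta(10, 10), each `me` normal(0, 0.3),
#' `beta_alpha` half-normal(3), `beta_d` normal(5, 3), `t0` normal(0.3, 0.1)
#' truncated to (0, min RT). Override any element with the same names.
#'
#' @return named list of log-prior density functions.
#' @export
default_ddm_priors <- function() {
  list(
    k = function(x) dnorm(x, 0, 10, log = TRUE),
    a = function(x) dgamma(x, shape = 2, scale = 1, log = TRUE),
    z = function(x) dbeta(x, 10, 10, log = TRUE),
    me = function(x) dnorm(x, 0, 0.3, log = TRUE),
    beta_alpha = function(x) dnorm(x, 0, 3, log = TRUE),
    beta_d = function(x) dnorm(x, 5, 3, log = TRUE),
    t0 = function(x) dnorm(x, 0.3, 0.1, log = TRUE)
  )
}

# names of the free parameters in the optimisation vector
DDM_PAR_NAMES <- c("k", "a", "beta_alpha", "beta_d", "t0",
                   "me.ref-large", "me.ref-small",
                   "z.ref-large", "z.ref-small")

ddm_par_vector <- function(params) {
  c(k = params$k, a = params$a, beta_alpha = params$beta_alpha,
    beta_d = params$beta_d, t0 = params$t0,
    setNames(params$me_by_context, paste0("me.", DDM_CONTEXTS)),
    setNames(params$z_by_context, paste0("z.", DDM_CONTEXTS)))
}

ddm_par_object <- function(v) {
  ddm_params(k = v[["k"]], a = v[["a"]], beta_alpha = v[["beta_alpha"]],
             beta_d = v[["beta_d"]], t0 = v[["t0"]],
             me_by_context = setNames(v[paste0("me.", DDM_CONTEXTS)], DDM_CONTEXTS),
             z_by_context = setNames(v[paste0("z.", DDM_CONTEXTS)], DDM_CONTEXTS))
}

# unconstrained <-> natural transforms for the free parameters
ddm_to_unconstrained <- function(v, max_t0) {
  c(log(v[["k"]]), log(v[["a"]]), log(max(v[["beta_alpha"]], 1e-6)),
    v[["beta_d"]], qlogis(min(max(v[["t0"]] / max_t0, 1e-6), 1 - 1e-6)),
    v[["me.ref-large"]], v[["me.ref-small"]],
    qlogis(v[["z.ref-large"]]), qlogis(v[["z.ref-small"]]))
}

ddm_from_unconstrained <- function(u, max_t0) {
  setNames(c(exp(u[1]), exp(u[2]), exp(u[3]), u[4], max_t0 * plogis(u[5]),
             u[6], u[7], plogis(u[8]), plogis(u[9])), DDM_PAR_NAMES)
}

#' Trial-wise log-likelihood of choice and RT under the DDM
#'
#' Log density of each trial's (choice, rt - t0) under the numerical
#' first-passage-time distribution at the trial's coherence and reward
#' context. Densities are linearly interpolated in time between grid points
#' and floored at `floor` to avoid -Inf.
#'
#' @param params a [ddm_params()] object.
#' @param trials trial table.
#' @param dt,dx solver resolution (see [first_passage_grid()]).
#' @param horizon solver horizon (s).
#' @param floor density floor (1/s).
#' @return total log-likelihood (scalar).
#' @export
ddm_loglik <- function(params, trials, dt = 0.005, dx = 0.06, horizon = 10,
                       floor = 1e-10) {
  trials <- validate_trial_table(trials)
  cond <- ddm_condition_data(trials)
  ddm_loglik_cond(params, cond, dt = dt, dx = dx, horizon = horizon,
                  floor = floor)
}

# Pre-grouped trial data for repeated likelihood evaluation: one cell per
# unique (reward context, signed coherence), with the RTs of each choice.
ddm_condition_data <- function(trials) {
  key <- interaction(trials$reward_context, trials$signed_coherence,
                     drop = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  list(
    context = vapply(idx, function(i) trials$reward_context[i[1]], numeric(1)),
    coherence = vapply(idx, function(i) trials$signed_coherence[i[1]],
                       numeric(1)),
    rt_upper = lapply(idx, function(i) trials$rt_s[i][trials$choice[i] > 0]),
    rt_lower = lapply(idx, function(i) trials$rt_s[i][trials$choice[i] < 0])
  )
}

ddm_loglik_cond <- function(params, cond, dt = 0.005, dx = 0.06,
                            horizon = 10, floor = 1e-10) {
  ctx <- context_label(cond$context)
  drift <- params$k * (cond$coherence + params$me_by_context[ctx])
  z <- params$z_by_context[ctx]
  cpp_ddm_loglik(drift, z, params$a, params$beta_alpha, params$beta_d,
                 params$t0, dt, dx, horizon, 0.25, 1e-7,
                 cond$rt_upper, cond$rt_lower, floor)
}

ddm_log_prior <- function(v, priors) {
  priors$k(v[["k"]]) + priors$a(v[["a"]]) +
    priors$beta_alpha(v[["beta_alpha"]]) + priors$beta_d(v[["beta_d"]]) +
    priors$t0(v[["t0"]]) +
    priors$me(v[["me.ref-large"]]) + priors$me(v[["me.ref-small"]]) +
    priors$z(v[["z.ref-large"]]) + priors$z(v[["z.ref-small"]])
}

#' MAP fit of the collapsing-bound DDM to a session
#'
#' Maximises the log posterior (trial-wise choice/RT likelihood from the
#' numerical first-passage solver, plus priors) over the nine model
#' parameters: shared `k, a, beta_alpha, beta_d, t0` and context-specific
#' `me, z`. Optimisation is gradient-free (Nelder-Mead) on unconstrained
#' transformed parameters, multi-started from prior draws; the best run is
#' polished with a restart and the run with the highest log posterior is
#' returned together with every run's score.
#'
#' @param trials trial table with both reward contexts present and positive
#'   RTs.
#' @param priors log-prior list, see [default_ddm_priors()].
#' @param n_runs number of optimisation starts (>= 5).
#' @param seed integer seed controlling the start jitter (fit is
#'   deterministic given data, seed and n_runs).
#' @param dt,dx solver resolution used inside the likelihood.
#' @param fixed optional named list of parameters to hold at given values
#'   and exclude from optimisation: any of `k`, `a`, `beta_alpha`,
#'   `beta_d`, `t0`, `me_by_context` (length 2). The context-specific `z`
#'   values are always free.
#' @param maxit Nelder-Mead iteration cap per run.
#' @return An object of class `ddm_fit`: `params` ([ddm_params()] at the MAP),
#'   `log_posterior`, `loglik`, `per_run_log` (each run's best log posterior),
#'   `se` (posterior-curvature standard errors on the natural scale),
#'   `converged`, `n_trials`.
#' @export
fit_ddm_map <- function(trials, priors = default_ddm_priors(), n_runs = 5L,
                        seed = 1L, dt = 0.005, dx = 0.06, fixed = NULL,
                        maxit = 400L) {
  trials <- validate_trial_table(trials)
  if (n_runs < 5L) stop("n_runs must be >= 5")
  if (length(unique(trials$reward_context)) < 2L)
    stop("both reward contexts must be present")
  if (any(trials$rt_s <= 0)) stop("all RTs must be > 0")
  min_rt <- min(trials$rt_s)
  max_t0 <- min_rt  # t0 must not exceed the fastest RT
  horizon <- max(5, 2 * max(trials$rt_s))

  fixed_names <- character(0)
  fixed_flat <- numeric(0)
  if (!is.null(fixed)) {
    if ("me_by_context" %in% names(fixed)) {
      me <- expand_context(fixed$me_by_context, "me_by_context")
      fixed$me_by_context <- NULL
      fixed <- c(fixed, setNames(as.list(me), paste0("me.", DDM_CONTEXTS)))
    }
    bad <- setdiff(names(fixed), setdiff(DDM_PAR_NAMES, paste0("z.", DDM_CONTEXTS)))
    if (length(bad)) stop("fixed cannot hold: ", paste(bad, collapse = ", "))
    fixed_names <- names(fixed)
    fixed_flat <- unlist(fixed)
  }
  free <- setdiff(DDM_PAR_NAMES, fixed_names)
  free_idx <- match(free, DDM_PAR_NAMES)

  assemble <- function(u_free) {
    u <- numeric(9)
    full0 <- c(k = 5, a = 1.5, beta_alpha = 2, beta_d = 4, t0 = 0.7 * min_rt,
               `me.ref-large` = 0, `me.ref-small` = 0,
               `z.ref-large` = 0.5, `z.ref-small` = 0.5)
    full0[fixed_names] <- fixed_flat[fixed_names]
    u <- ddm_to_unconstrained(full0, max_t0)
    u[free_idx] <- u_free
    ddm_from_unconstrained(u, max_t0)
  }

  cond <- ddm_condition_data(trials)
  neg_log_post <- function(u_free) {
    v <- assemble(u_free)
    p <- tryCatch(ddm_par_object(v), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- ddm_loglik_cond(p, cond, dt = dt, dx = dx, horizon = horizon)
    lp <- ddm_log_prior(v, priors)
    out <- -(ll + lp)
    if (!is.finite(out)) 1e10 else out
  }

  # deterministic start set: one default start, the rest jittered prior draws
  set.seed(as.integer(seed))
  starts <- vector("list", n_runs)
  v0 <- c(k = 5, a = 1.5, beta_alpha = 2, beta_d = 4, t0 = 0.7 * min_rt,
          `me.ref-large` = 0, `me.ref-small` = 0,
          `z.ref-large` = 0.5, `z.ref-small` = 0.5)
  starts[[1]] <- ddm_to_unconstrained(v0, max_t0)[free_idx]
  for (r in seq_len(n_runs)[-1]) {
    vr <- c(k = abs(rnorm(1, 0, 10)) + 0.5, a = rgamma(1, 2, scale = 1) + 0.2,
            beta_alpha = abs(rnorm(1, 0, 3)) + 0.1, beta_d = rnorm(1, 5, 3),
            t0 = runif(1, 0.2, 0.9) * min_rt,
            `me.ref-large` = rnorm(1, 0, 0.1),
            `me.ref-small` = rnorm(1, 0, 0.1),
            `z.ref-large` = rbeta(1, 10, 10),
            `z.ref-small` = rbeta(1, 10, 10))
    starts[[r]] <- ddm_to_unconstrained(vr, max_t0)[free_idx]
  }

  runs <- lapply(starts, function(st) {
    tryCatch(
      optim(st, neg_log_post, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-6)),
      error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (sum(ok) < n_runs)
    stop(sprintf("%d of %d optimisation runs failed", sum(!ok), n_runs))
  per_run_log <- -vapply(runs, `[[`, numeric(1), "value")
  best <- which.max(per_run_log)
  # polish the winning run with a restart (fresh simplex)
  pol <- optim(runs[[best]]$par, neg_log_post, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
  if (-pol$value > per_run_log[best]) {
    runs[[best]] <- pol
    per_run_log[best] <- -pol$value
  }
  u_hat <- runs[[best]]$par
  v_hat <- assemble(u_hat)
  params <- ddm_par_object(v_hat)

  if (params$t0 >= min_rt - 1e-6)
    warning("t0 reached the fastest RT: boundary solution")

  # curvature SEs: numerical Hessian in the unconstrained space, mapped to
  # the natural scale by the delta method
  se <- rep(NA_real_, length(free))
  names(se) <- free
  # wide finite-difference steps: the discretised likelihood has ~1e-2-nat
  # ripples that would swamp a small-step second difference
  H <- tryCatch(optimHess(u_hat, neg_log_post,
                          control = list(ndeps = rep(0.05, length(u_hat)))),
                error = function(e) NULL)
  if (!is.null(H)) {
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      sd_u <- sqrt(pmax(diag(cv), 0))
      eps <- 1e-5
      jac <- vapply(seq_along(u_hat), function(i) {
        up <- u_hat; up[i] <- up[i] + eps
        dn <- u_hat; dn[i] <- dn[i] - eps
        (assemble(up)[free_idx[i]] - assemble(dn)[free_idx[i]]) / (2 * eps)
      }, numeric(1))
      se <- setNames(abs(jac) * sd_u, free)
    }
  }

  structure(list(params = params,
                 log_posterior = per_run_log[best],
                 loglik = ddm_loglik(params, trials, dt = dt, dx = dx,
                                     horizon = horizon),
                 per_run_log = per_run_log, se = se,
                 converged = runs[[best]]$convergence == 0L,
                 n_trials = nrow(trials), fixed = fixed,
                 dt = dt, dx = dx),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("DDM MAP fit: %d trials, log posterior %.2f (best of %d runs)\n",
              x$n_trials, x$log_posterior, length(x$per_run_log)))
  print(x$params)
  b <- compute_biases(x$params)
  cat(sprintf("  delta_drift = %+.4f, delta_bound = %+.4f\n",
              b$delta_drift, b$delta_bound))
  invisible(x)
}

#' Reward biases in drift and bound from fitted parameters
#'
#' The drift-rate bias is the difference in the fitted evidence offsets
#' between the two reward contexts, `me[ref-large] - me[ref-small]`; the
#' bound bias is `z[ref-large] - z[ref-small]`. Positive values indicate a
#' bias toward the large-reward choice.
#'
#' @param params a [ddm_params()] object or a `ddm_fit`.
#' @param orientation label recording which choice is "reference"
#'   (upper bound); carried through for reporting.
#' @return An object of class `bias_estimates`: list with `delta_drift`
#'   (coherence units), `delta_bound` (unitless) and `orientation`.
#' @export
compute_biases <- function(params, orientation = "reference") {
  if (inherits(params, "ddm_fit")) params <- params$params
  stopifnot(inherits(params, "ddm_params"))
  me <- params$me_by_context
  z <- params$z_by_context
  if (any(is.na(me)) || any(is.na(z))) stop("both contexts must be fitted")
  structure(list(
    delta_drift = unname(me[["ref-large"]] - me[["ref-small"]]),
    delta_bound = unname(z[["ref-large"]] - z[["ref-small"]]),
    orientation = orientation), class = "bias_estimates")
}

#' @export
print.bias_estimates <- function(x, ...) {
  cat(sprintf(
    "Reward biases (positive = toward large-reward choice; reference = %s)\n  delta_drift = %+.4f (coherence units)\n  delta_bound = %+.4f\n",
    x$orientation, x$delta_drift, x$delta_bound))
  invisible(x)
}
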