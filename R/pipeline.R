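#' Default analysis configuration
#'
#' Thresholds and resolutions used by the pipeline, overridable via a YAML
#' file (only keys present in the file are replaced).
#'
#' @param path optional YAML file of overrides.
#' @return named list: `alpha` (per-test criterion), `bonferroni_n`
#'   (population comparisons), `n_runs` (DDM starts), `solver_dt`,
#'   `solver_dx`, `running_window`, `running_step`, `min_window_trials`,
#'   `slope_sigma`, `slope_window`, `slope_step`, `min_latency`, `n_null`
#'   (shuffle regressions).
#' @export
default_config <- function(path = NULL) {
  cfg <- list(alpha = 0.05, bonferroni_n = 72L, n_runs = 5L,
              solver_dt = 0.005, solver_dx = 0.06,
              running_window = 0.15, running_step = 0.01,
              min_window_trials = 10L, slope_sigma = 0.020,
              slope_window = 0.2, slope_step = 0.02, min_latency = 0.1,
              n_null = 100L)
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Run the full per-session analysis chain
#'
#' Executes, in order: logistic fit, DDM MAP fit and bias extraction on the
#' session's behaviour; then per neuron the epoch and running regressions,
#' classification, slope series, congruency inputs and baseline split. A
#' stage failure for one neuron skips that neuron's downstream stages with a
#' log entry; behavioural failures abort. The returned bundle carries a
#' manifest (config snapshot, input checksums, seed) so outputs are
#' traceable.
#'
#' @param trials trial table (data.frame) or path to a trial-table CSV.
#' @param neurons list of [neuron_recording()] objects, or paths to spike
#'   JSONL files (read against `trials`).
#' @param config configuration list from [default_config()].
#' @param seed integer seed (DDM fit starts and shuffle draws).
#' @param fit_fixed optional `fixed` list forwarded to the DDM fits.
#' @return list of class `session_bundle`: `logistic`, `ddm_fit`, `biases`,
#'   `neurons` (per-neuron results), `manifest`.
#' @export
run_session <- function(trials, neurons = list(), config = default_config(),
                        seed = 1L, fit_fixed = NULL) {
  input_files <- character(0)
  if (is.character(trials)) {
    input_files <- c(input_files, trials)
    trials <- read_trial_table(trials)
  }
  trials <- validate_trial_table(trials)
  if (length(neurons) && is.character(neurons[[1]])) {
    input_files <- c(input_files, unlist(neurons))
    neurons <- lapply(neurons, read_spike_trains, trials = trials)
  }

  logistic <- fit_logistic(trials)
  ddm_fit <- fit_ddm_map(trials, n_runs = config$n_runs, seed = seed,
                         dt = config$solver_dt, dx = config$solver_dx,
                         fixed = fit_fixed)
  biases <- compute_biases(ddm_fit)

  epochs <- define_epochs(trials)
  neuron_results <- lapply(neurons, function(nr) {
    tryCatch({
      ep_rt <- epoch_regression(nr, epochs, design = "rt")
      ep_coh <- epoch_regression(nr, epochs, design = "coherence")
      cls <- classify_neurons(ep_rt, nr, alpha = config$alpha)
      run_rt <- running_regression(nr, "motion", "rt",
                                   window = config$running_window,
                                   step = config$running_step,
                                   min_trials = config$min_window_trials)
      run_sacc <- running_regression(nr, "saccade", "rt",
                                     window = config$running_window,
                                     step = config$running_step,
                                     min_trials = config$min_window_trials)
      slopes <- if (cls$choice_selective) {
        nr$preferred_choice <- cls$preferred_choice
        slope_series(nr, "motion", "preferred",
                     sigma = config$slope_sigma,
                     window = config$slope_window, step = config$slope_step)
      } else NULL
      split <- tryCatch(split_by_baseline(nr, epochs),
                        warning = function(w) suppressWarnings(
                          split_by_baseline(nr, epochs)))
      list(neuron_id = nr$neuron_id, region = nr$region, ok = TRUE,
           epoch_rt = ep_rt, epoch_coherence = ep_coh, classification = cls,
           running_motion = run_rt, running_saccade = run_sacc,
           slope_series = slopes, baseline_split = split)
    }, error = function(e) {
      message("neuron ", nr$neuron_id, " failed: ", conditionMessage(e))
      list(neuron_id = nr$neuron_id, region = nr$region, ok = FALSE,
           error = conditionMessage(e))
    })
  })

  manifest <- list(
    seed = as.integer(seed),
    config = config,
    inputs = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    n_trials = nrow(trials), n_neurons = length(neurons),
    stages = c(behavior = TRUE,
               neurons_ok = sum(vapply(neuron_results, `[[`, logical(1), "ok"))))
  structure(list(session_id = trials$session_id[1], logistic = logistic,
                 ddm_fit = ddm_fit, biases = biases,
                 neurons = neuron_results, manifest = manifest),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("Session bundle %s: %d trials, %d neurons (%d ok)\n",
              x$session_id, x$manifest$n_trials, length(x$neurons),
              x$manifest$stages[["neurons_ok"]]))
  print(x$biases)
  invisible(x)
}

#' Aggregate session bundles into population summaries
#'
#' Pools per-neuron results across sessions: population fraction tables of
#' significant regression coefficients, the slope-ratio vs drift-bias
#' correlation over eligible choice-selective neurons, congruent fractions
#' of reward-context modulation against the bound bias, and (when split DDM
#' comparisons are supplied) the population t-test on bound-bias
#' differences.
#'
#' @param bundles list of `session_bundle` objects.
#' @param config configuration list.
#' @return list of class `population_summary`: `fractions`,
#'   `ratio_correlation`, `congruency`, `n_neurons`.
#' @export
run_population <- function(bundles, config = default_config()) {
  if (!length(bundles)) stop("need at least one session bundle")
  ok_neurons <- list()
  for (b in bundles) for (nr in b$neurons) if (isTRUE(nr$ok)) {
    nr$delta_drift <- b$biases$delta_drift
    nr$delta_bound <- b$biases$delta_bound
    ok_neurons[[length(ok_neurons) + 1L]] <- nr
  }
  if (!length(ok_neurons)) stop("no successfully analysed neurons")

  ep <- do.call(rbind, lapply(ok_neurons, function(nr) {
    d <- nr$epoch_rt
    d$region <- nr$region
    d
  }))
  fractions <- population_fractions(ep, alpha = config$alpha,
                                    n_comparisons = config$bonferroni_n)

  sel <- Filter(function(nr) isTRUE(nr$classification$choice_selective) &&
                  !is.null(nr$slope_series) && nrow(nr$slope_series),
                ok_neurons)
  ratio_correlation <- NULL
  if (length(sel) >= 3L) {
    tab <- slope_summary_table(lapply(sel, `[[`, "slope_series"),
                               alpha = config$alpha,
                               min_latency = config$min_latency)
    tab$delta_drift <- vapply(sel, `[[`, numeric(1), "delta_drift")
    el <- tab$eligible
    if (sum(el) >= 3L)
      ratio_correlation <- ratio_bias_correlation(tab$ratio[el],
                                                  tab$delta_drift[el])
  }

  congr <- NULL
  sel_ids <- vapply(sel, `[[`, character(1), "neuron_id")
  if (length(sel) >= 2L) {
    coefs <- do.call(rbind, lapply(sel, function(nr) {
      rr <- nr$running_motion
      rows <- rr[rr$regressor == "reward_context" & !rr$excluded, ]
      pref_sign <- if (nr$classification$preferred_choice == "reference")
        1 else -1
      data.frame(neuron_id = nr$neuron_id, center = rows$center,
                 beta = pref_sign * rows$beta, p = rows$p)
    }))
    biases <- data.frame(
      neuron_id = sel_ids,
      delta_bound = vapply(sel, function(nr) {
        pref_sign <- if (nr$classification$preferred_choice == "reference")
          1 else -1
        pref_sign * nr$delta_bound
      }, numeric(1)))
    congr <- congruency_analysis(coefs, biases, "pre-motion",
                                 alpha = config$alpha)
  }

  structure(list(fractions = fractions,
                 ratio_correlation = ratio_correlation,
                 congruency = congr, n_neurons = length(ok_neurons)),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary over %d neurons\n", x$n_neurons))
  if (!is.null(x$ratio_correlation))
    cat(sprintf("  ratio-bias correlation: r = %.3f (p = %.3g, n = %d)\n",
                x$ratio_correlation$r, x$ratio_correlation$p,
                x$ratio_correlation$n))
  if (!is.null(x$congruency))
    cat(sprintf("  pre-motion congruent fraction (mean over bins): %.3f\n",
                mean(x$congruency$by_bin$fraction, na.rm = TRUE)))
  invisible(x)
}
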