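#' Congruency of reward-context modulation with the bound bias
#'
#' If a reward bias in relative bound heights is implemented as an offset to
#' the accumulation process, a choice-selective neuron whose preferred
#' choice is paired with the large reward should raise its baseline firing
#' before motion onset (offset to the start of accumulation) or lower its
#' firing before saccade onset (offset to the end). With coefficients
#' expressed in the preferred-choice frame (positive = more firing when the
#' preferred choice is paired with the large reward), a significant
#' reward-context coefficient is congruent with the behavioural bound bias
#' when its sign matches `sign(delta_bound)` in the pre-motion period and
#' `-sign(delta_bound)` in the pre-saccade period. Per time bin, the
#' congruent fraction across neurons is tested against 0.5 by chi-square
#' (uncorrected, to reduce false negatives).
#'
#' @param coefs data.frame with columns `neuron_id`, `center`, `beta`
#'   (reward-context coefficient, preferred-choice frame), `p` — typically
#'   the `reward_context` rows of a [running_regression()] per neuron.
#' @param biases data.frame with columns `neuron_id`, `delta_bound`
#'   (preferred-choice frame, i.e. fitted with the preferred choice as the
#'   upper bound). Neurons with `delta_bound == 0` are excluded.
#' @param period `"pre-motion"` or `"pre-saccade"`.
#' @param alpha significance criterion for the per-bin coefficients.
#' @return list of class `congruency_result`: `flags` (per neuron x bin
#'   rows with `congruent` defined only where the coefficient is
#'   significant) and `by_bin` (per bin `n_sig`, `n_congruent`, `fraction`,
#'   `p_vs_half`, `sig`).
#' @export
congruency_analysis <- function(coefs, biases,
                                period = c("pre-motion", "pre-saccade"),
                                alpha = 0.05) {
  period <- match.arg(period)
  need <- c("neuron_id", "center", "beta", "p")
  if (!all(need %in% names(coefs)))
    stop("coefs needs columns: ", paste(need, collapse = ", "))
  db <- setNames(biases$delta_bound, biases$neuron_id)
  db <- db[db != 0 & !is.na(db)]
  flags <- coefs[coefs$neuron_id %in% names(db), need]
  flags$delta_bound <- db[flags$neuron_id]
  expect_sign <- if (period == "pre-motion") 1 else -1
  sig <- is.finite(flags$p) & flags$p < alpha
  flags$congruent <- NA
  flags$congruent[sig] <- sign(flags$beta[sig]) ==
    expect_sign * sign(flags$delta_bound[sig])
  by_bin <- do.call(rbind, lapply(sort(unique(flags$center)), function(ct) {
    f <- flags$congruent[flags$center == ct]
    f <- f[!is.na(f)]
    n <- length(f)
    k <- sum(f)
    pv <- if (n > 0)
      suppressWarnings(chisq.test(c(k, n - k), p = c(0.5, 0.5))$p.value)
    else NA_real_
    data.frame(center = ct, n_sig = n, n_congruent = k,
               fraction = if (n > 0) k / n else NA_real_,
               p_vs_half = pv, sig = isTRUE(pv < alpha))
  }))
  structure(list(flags = flags, by_bin = by_bin, period = period),
            class = "congruency_result")
}

#' @export
print.congruency_result <- function(x, ...) {
  cat(sprintf("Congruency (%s): %d bins, mean congruent fraction %.3f\n",
              x$period, nrow(x$by_bin),
              mean(x$by_bin$fraction, na.rm = TRUE)))
  invisible(x)
}

#' Split trials by baseline activity before motion onset
#'
#' Within each reward context, trials are split at the median of the
#' pre-motion (epoch #3) firing rate; the split is rank-based with ties
#' broken by trial index, the median trial going to the low half. The
#' neuron's preferred reward context is the context with the higher mean
#' epoch-3 rate. "Large modulation" trials are the high-rate half in the
#' preferred context plus the low-rate half in the other context — trials
#' on which the neuron's reward-context modulation was strong — and "small
#' modulation" trials are the complement. Both groups contain both
#' contexts.
#'
#' @param recording a [neuron_recording()].
#' @param epochs optional [define_epochs()] result.
#' @param min_trials groups smaller than this are flagged underpowered.
#' @return list with `large_mod` and `small_mod` trial tables,
#'   `preferred_context` (+1/-1), `underpowered`.
#' @export
split_by_baseline <- function(recording, epochs = NULL, min_trials = 20L) {
  stopifnot(inherits(recording, "neuron_recording"))
  trials <- recording$trials
  if (is.null(epochs)) epochs <- define_epochs(trials)
  e3 <- which(EPOCH_NAMES == "pre_motion_400")
  counts <- epoch_spike_counts(recording$spikes, epochs$start[, e3],
                               epochs$end[, e3])
  rate <- counts / 0.4
  pref_ctx <- if (mean(rate[trials$reward_context == 1]) >=
                  mean(rate[trials$reward_context == -1])) 1 else -1
  half <- function(ctx) {
    i <- which(trials$reward_context == ctx)
    ord <- i[order(rate[i], trials$trial_index[i])]
    n_low <- ceiling(length(i) / 2)
    list(low = ord[seq_len(n_low)],
         high = ord[setdiff(seq_along(ord), seq_len(n_low))])
  }
  hp <- half(pref_ctx)
  ho <- half(-pref_ctx)
  large_idx <- sort(c(hp$high, ho$low))
  small_idx <- sort(c(hp$low, ho$high))
  underpowered <- min(length(large_idx), length(small_idx)) < min_trials
  if (underpowered)
    warning("baseline split produced a group with fewer than ", min_trials,
            " trials")
  list(large_mod = trials[large_idx, ], small_mod = trials[small_idx, ],
       preferred_context = pref_ctx, underpowered = underpowered)
}

#' Compare bound biases between baseline-split trial groups
#'
#' Fits the collapsing-bound DDM separately to each neuron's large- and
#' small-modulation trial groups (from [split_by_baseline()]), takes the
#' difference of the fitted bound biases
#' `delta_bound(large) - delta_bound(small)` per neuron, and tests the mean
#' difference against zero across neurons with a one-sample t-test.
#'
#' @param splits list of per-neuron splits, each a list with `large_mod`
#'   and `small_mod` trial tables (and optionally `neuron_id`).
#' @param priors,seed,n_runs,dt,dx,fixed,maxit passed to [fit_ddm_map()];
#'   `fixed` can hold the non-bound parameters at session-level values to
#'   stabilise the per-group refits.
#' @return list of class `split_result`: `per_neuron` data.frame
#'   (`delta_bound_large_mod`, `delta_bound_small_mod`, `difference`),
#'   `t_test` (htest), `n_failed`.
#' @export
split_ddm_compare <- function(splits, priors = default_ddm_priors(),
                              seed = 1L, n_runs = 5L, dt = 0.005, dx = 0.06,
                              fixed = NULL, maxit = 400L) {
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    id <- if (!is.null(sp$neuron_id)) sp$neuron_id else as.character(i)
    res <- tryCatch({
      # same start seed for both groups: identical inputs give an exactly
      # zero difference
      fl <- fit_ddm_map(sp$large_mod, priors = priors, n_runs = n_runs,
                        seed = seed + i, dt = dt, dx = dx, fixed = fixed,
                        maxit = maxit)
      fs <- fit_ddm_map(sp$small_mod, priors = priors, n_runs = n_runs,
                        seed = seed + i, dt = dt, dx = dx, fixed = fixed,
                        maxit = maxit)
      c(compute_biases(fl)$delta_bound, compute_biases(fs)$delta_bound)
    }, error = function(e) {
      message("split fit failed for neuron ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = id, delta_bound_large_mod = res[1],
      delta_bound_small_mod = res[2], difference = res[1] - res[2])
  }
  per_neuron <- do.call(rbind, rows)
  tt <- if (!is.null(per_neuron) && nrow(per_neuron) >= 2L)
    t.test(per_neuron$difference) else NULL
  structure(list(per_neuron = per_neuron, t_test = tt, n_failed = n_failed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  n <- if (is.null(x$per_neuron)) 0L else nrow(x$per_neuron)
  cat(sprintf("Baseline-split DDM comparison: %d neurons (%d failed)\n",
              n, x$n_failed))
  if (!is.null(x$t_test))
    cat(sprintf("  mean difference %.4f, t-test p = %.4g\n",
                mean(x$per_neuron$difference), x$t_test$p.value))
  invisible(x)
}

#' Heatmap-ready matrix of normalised reward-context coefficients
#'
#' Neuron x time-bin matrix of running reward-context coefficients,
#' normalised per neuron by the maximal absolute coefficient;
#' non-significant bins are set to `NA`.
#'
#' @param coefs as in [congruency_analysis()].
#' @param alpha significance criterion.
#' @return numeric matrix (rows = neurons, columns = bin centers).
#' @export
congruency_matrix <- function(coefs, alpha = 0.05) {
  ids <- unique(coefs$neuron_id)
  centers <- sort(unique(coefs$center))
  m <- matrix(NA_real_, length(ids), length(centers),
              dimnames = list(ids, sprintf("%.3f", centers)))
  for (i in seq_along(ids)) {
    sub <- coefs[coefs$neuron_id == ids[i], ]
    mx <- max(abs(sub$beta), na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) next
    sig <- is.finite(sub$p) & sub$p < alpha
    m[i, match(sub$center[sig], centers)] <- sub$beta[sig] / mx
  }
  m
}
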