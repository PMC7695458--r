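#' Spike-count regression design matrices
#'
#' Builds the regressors of the coherence-based and RT-based multiple linear
#' regression designs from a trial table. Indicator coding: `choice` is +1
#' for the reference (contralateral/up) choice, -1 otherwise;
#' `reward_context` is +1 when the reference choice is paired with the large
#' reward; `reward_size` is +1 when a large reward is expected for the
#' chosen target (the product of the other two). The coherence design
#' splits unsigned coherence by choice (`coh_contra`, `coh_ipsi`) with
#' reward-size interactions; the RT design instead uses mean-subtracted RTs
#' split by choice, the means taken within each reward-context x choice
#' cell.
#'
#' @param trials trial table rows entering the regression.
#' @param design `"coherence"` or `"rt"`.
#' @return data.frame of regressor columns (no intercept).
#' @export
regression_design <- function(trials, design = c("coherence", "rt")) {
  design <- match.arg(design)
  ch <- trials$choice
  rc <- trials$reward_context
  rs <- ch * rc
  if (design == "coherence") {
    coh <- abs(trials$signed_coherence)
    out <- data.frame(choice = ch, reward_context = rc, reward_size = rs,
                      coh_contra = coh * (ch > 0), coh_ipsi = coh * (ch < 0))
    out$rewcoh_contra <- out$coh_contra * rs
    out$rewcoh_ipsi <- out$coh_ipsi * rs
  } else {
    cell <- interaction(rc, ch, drop = TRUE)
    rt_ms <- trials$rt_s - cell_mean(trials$rt_s, cell)
    out <- data.frame(choice = ch, reward_context = rc, reward_size = rs,
                      rt_contra = rt_ms * (ch > 0), rt_ipsi = rt_ms * (ch < 0))
    out$rewrt_contra <- out$rt_contra * rs
    out$rewrt_ipsi <- out$rt_ipsi * rs
  }
  out
}

cell_mean <- function(x, g) {
  m <- tapply(x, g, mean)
  as.numeric(m[as.character(g)])
}

# OLS of counts on a design data.frame; returns tidy coefficient rows.
# Aliased (rank-deficient) columns are dropped with a warning.
fit_count_regression <- function(counts, X) {
  df <- cbind(data.frame(.count = counts), X)
  fit <- lm(.count ~ ., data = df)
  sm <- summary(fit)
  co <- coef(sm)
  aliased <- setdiff(c("(Intercept)", names(X)),
                     rownames(co))
  if (length(aliased))
    warning("aliased regressors dropped: ", paste(aliased, collapse = ", "))
  rows <- data.frame(
    regressor = sub("^\\(Intercept\\)$", "intercept", rownames(co)),
    beta = co[, 1], se = co[, 2], p = co[, 4], row.names = NULL)
  # exact-fit / zero-variance guard: NaN p from 0/0 means beta is exact
  rows$p[is.nan(rows$p)] <- 1
  attr(rows, "r_squared") <- sm$r.squared
  attr(rows, "n_trials") <- length(counts)
  rows
}

#' Epoch-wise spike-count regression
#'
#' Ordinary least squares of the spike counts in each of the eight task
#' epochs on the chosen design ([regression_design()]), over correct trials
#' only, with per-coefficient t-tests. Degenerate epoch windows are flagged
#' and skipped.
#'
#' @param recording a [neuron_recording()].
#' @param epochs an [define_epochs()] result for the same trials; computed
#'   from the recording when `NULL`.
#' @param design `"coherence"` or `"rt"`.
#' @return data.frame of class `epoch_regression` with columns `epoch`
#'   (1-8), `epoch_name`, `regressor`, `beta`, `se`, `p`, plus `n_trials`,
#'   `r_squared`, `degenerate` per epoch.
#' @export
epoch_regression <- function(recording, epochs = NULL,
                             design = c("coherence", "rt")) {
  design <- match.arg(design)
  stopifnot(inherits(recording, "neuron_recording"))
  trials <- recording$trials
  if (is.null(epochs)) epochs <- define_epochs(trials)
  keep <- which(trials$correct == 1)
  X <- regression_design(trials[keep, ], design)
  out <- vector("list", 8L)
  for (e in seq_len(8L)) {
    degen <- any(epochs$degenerate[keep, e])
    if (degen) {
      rows <- data.frame(regressor = c("intercept", names(X)),
                         beta = NA_real_, se = NA_real_, p = NA_real_)
      attr(rows, "r_squared") <- NA_real_
      attr(rows, "n_trials") <- length(keep)
    } else {
      counts <- epoch_spike_counts(recording$spikes[keep],
                                   epochs$start[keep, e],
                                   epochs$end[keep, e])
      rows <- fit_count_regression(counts, X)
    }
    rows$epoch <- e
    rows$epoch_name <- EPOCH_NAMES[e]
    rows$n_trials <- attr(rows, "n_trials")
    rows$r_squared <- attr(rows, "r_squared")
    rows$degenerate <- degen
    out[[e]] <- rows
  }
  res <- do.call(rbind, out)
  res$neuron_id <- recording$neuron_id
  res$design <- design
  class(res) <- c("epoch_regression", "data.frame")
  res
}

#' Sliding-window spike-count regression
#'
#' Runs the chosen regression design on spike counts in 150 ms windows
#' stepped every 10 ms, on activity aligned to target, motion or saccade
#' onset. Correct trials only; a trial enters a window only when the window
#' lies within the trial's recorded span, and windows with fewer than 10
#' qualifying correct trials are marked excluded (coefficients `NA`).
#'
#' @param recording a [neuron_recording()].
#' @param alignment `"target"`, `"motion"` or `"saccade"`.
#' @param design `"coherence"` or `"rt"`.
#' @param span length-2 vector of window-center times (s) relative to the
#'   alignment event; defaults per alignment.
#' @param window window width (s).
#' @param step center spacing (s).
#' @param min_trials minimum correct trials per window.
#' @return data.frame of class `running_regression`: columns `alignment`,
#'   `center`, `regressor`, `beta`, `se`, `p`, `n_trials`, `excluded`.
#' @export
running_regression <- function(recording,
                               alignment = c("target", "motion", "saccade"),
                               design = c("coherence", "rt"), span = NULL,
                               window = 0.15, step = 0.01,
                               min_trials = 10L) {
  alignment <- match.arg(alignment)
  design <- match.arg(design)
  stopifnot(inherits(recording, "neuron_recording"))
  trials <- recording$trials
  if (is.null(span))
    span <- switch(alignment, target = c(-0.2, 0.8), motion = c(-0.4, 0.8),
                   saccade = c(-0.8, 0.4))
  ev <- switch(alignment, target = trials$t_target_on_s,
               motion = trials$t_motion_on_s, saccade = trials$t_saccade_on_s)
  keep <- which(trials$correct == 1)
  if (!length(keep)) stop("no correct trials")
  Xall <- regression_design(trials[keep, ], design)
  # recorded span per trial
  lo <- trials$t_target_on_s - 0.4
  hi <- trials$t_saccade_on_s + 0.6
  centers <- seq(span[1], span[2], by = step)
  reg_names <- c("intercept", names(Xall))
  out <- vector("list", length(centers))
  for (ci in seq_along(centers)) {
    w0 <- ev + centers[ci] - window / 2
    w1 <- ev + centers[ci] + window / 2
    ok <- keep[w0[keep] >= lo[keep] & w1[keep] <= hi[keep]]
    if (length(ok) < min_trials) {
      rows <- data.frame(regressor = reg_names, beta = NA_real_,
                         se = NA_real_, p = NA_real_)
      n_tr <- length(ok)
      excl <- TRUE
    } else {
      counts <- epoch_spike_counts(recording$spikes[ok], w0[ok], w1[ok])
      rows <- fit_count_regression(counts, Xall[match(ok, keep), ])
      n_tr <- length(ok)
      excl <- FALSE
    }
    rows$center <- centers[ci]
    rows$n_trials <- n_tr
    rows$excluded <- excl
    out[[ci]] <- rows
  }
  res <- do.call(rbind, out)
  if (all(res$excluded))
    message("running_regression: no window had >= ", min_trials,
            " correct trials")
  res$alignment <- alignment
  res$design <- design
  res$neuron_id <- recording$neuron_id
  class(res) <- c("running_regression", "data.frame")
  res
}

#' Shuffle null for the reward-context coefficient
#'
#' Reward contexts alternate in blocks, so spike-count drift over a session
#' can masquerade as reward-context coding. This control re-estimates the
#' regression `n_null` times, replacing the reward-context regressor with a
#' random contiguous segment (of the session's length) of a pool built by
#' concatenating reward-context sequences across neurons, which preserves
#' the blocked autocorrelation structure. The adjusted p-value is the
#' one-tailed magnitude rank `(1 + #{|beta_null| >= |beta_obs|}) / (1 + n_null)`.
#'
#' @param counts spike counts of the included (correct) trials.
#' @param trials the matching trial-table rows.
#' @param context_pool numeric vector of +1/-1 context values pooled across
#'   neurons; must be at least `nrow(trials) + n_null` long.
#' @param design `"coherence"` or `"rt"`.
#' @param n_null number of null regressions.
#' @param seed integer seed.
#' @return list with `observed_beta`, `null_betas`, `p_adjusted`.
#' @export
serial_correlation_null <- function(counts, trials, context_pool,
                                    design = c("coherence", "rt"),
                                    n_null = 100L, seed = 1L) {
  design <- match.arg(design)
  n <- nrow(trials)
  if (length(counts) != n) stop("counts and trials must match")
  if (length(context_pool) < n + n_null)
    stop("context pool shorter than n_trials + n_null")
  X <- regression_design(trials, design)
  obs <- fit_count_regression(counts, X)
  b_obs <- obs$beta[obs$regressor == "reward_context"]
  set.seed(as.integer(seed))
  starts <- sample.int(length(context_pool) - n + 1L, n_null, replace = TRUE)
  null_betas <- vapply(starts, function(s) {
    Xn <- X
    Xn$reward_context <- context_pool[s:(s + n - 1L)]
    fit <- suppressWarnings(fit_count_regression(counts, Xn))
    b <- fit$beta[fit$regressor == "reward_context"]
    if (length(b)) b else NA_real_
  }, numeric(1))
  k <- sum(abs(null_betas) >= abs(b_obs), na.rm = TRUE)
  list(observed_beta = b_obs, null_betas = null_betas,
       p_adjusted = (1 + k) / (1 + n_null))
}

#' Peak firing rate of a recording
#'
#' Maximum of the trial-averaged firing rate in 50 ms sliding windows
#' (10 ms steps) of activity aligned to motion and to saccade onset; used by
#' the inclusion filter.
#'
#' @param recording a [neuron_recording()].
#' @return peak rate (spikes/s).
#' @export
peak_firing_rate <- function(recording) {
  trials <- recording$trials
  peak <- 0
  for (al in c("motion", "saccade")) {
    ev <- if (al == "motion") trials$t_motion_on_s else trials$t_saccade_on_s
    span <- if (al == "motion") c(-0.4, 0.6) else c(-0.6, 0.4)
    centers <- seq(span[1], span[2], by = 0.01)
    rel <- lapply(seq_along(recording$spikes),
                  function(i) recording$spikes[[i]] - ev[i])
    all_rel <- unlist(rel)
    n <- length(rel)
    for (ct in centers) {
      r <- sum(all_rel >= ct - 0.025 & all_rel < ct + 0.025) / n / 0.05
      if (r > peak) peak <- r
    }
  }
  peak
}

#' Inclusion filter and choice-selectivity classification
#'
#' A neuron is included when its peak firing rate is at least 5 Hz and every
#' signed-coherence x reward-context cell has at least 5 finished trials and
#' at least 3 correct trials. It is choice-selective when the RT-design
#' choice coefficient is significant (p < `alpha`) with the same sign in
#' both the motion-viewing epoch (#5) and the pre-saccade epoch (#6); the
#' preferred choice is `"reference"` for positive coefficients, `"other"`
#' for negative ones.
#'
#' @param epoch_results an [epoch_regression()] result with `design == "rt"`.
#' @param recording the matching [neuron_recording()].
#' @param alpha significance criterion.
#' @return list with `included`, `peak_rate`, `min_finished`, `min_correct`,
#'   `choice_selective`, `preferred_choice`.
#' @export
classify_neurons <- function(epoch_results, recording, alpha = 0.05) {
  stopifnot(inherits(recording, "neuron_recording"))
  if (!all(c(5L, 6L) %in% epoch_results$epoch))
    stop("epochs 5 and 6 must be fitted for classification")
  if (!identical(unique(epoch_results$design), "rt"))
    stop("classification uses the RT-based design")
  trials <- recording$trials
  cell <- interaction(trials$signed_coherence, trials$reward_context,
                      drop = TRUE)
  fin <- table(cell)
  corr <- table(cell[trials$correct == 1])
  corr <- corr[names(fin)]
  corr[is.na(corr)] <- 0L
  peak <- peak_firing_rate(recording)
  included <- peak >= 5 && min(fin) >= 5L && min(corr) >= 3L

  b5 <- epoch_results[epoch_results$epoch == 5L &
                        epoch_results$regressor == "choice", ]
  b6 <- epoch_results[epoch_results$epoch == 6L &
                        epoch_results$regressor == "choice", ]
  sel <- isTRUE(b5$p < alpha && b6$p < alpha &&
                  sign(b5$beta) == sign(b6$beta))
  list(included = included, peak_rate = peak,
       min_finished = as.integer(min(fin)), min_correct = as.integer(min(corr)),
       choice_selective = sel,
       preferred_choice = if (!sel) "undefined"
       else if (b5$beta > 0) "reference" else "other")
}

#' Population fractions of significant neurons
#'
#' For each epoch and regressor category, the fraction of neurons whose
#' coefficient is significant at `alpha`. The per-choice coherence / RT
#' regressors and their reward interactions are pooled into "either choice"
#' categories (significant if either member is); the chance level for a
#' category pooling m regressors is `1 - (1 - alpha)^m`. Each fraction is
#' compared against chance, and regions against each other, by chi-square
#' tests at the Bonferroni-corrected criterion `alpha / n_comparisons`
#' (default 0.05/72: 8 epochs x 9 comparisons).
#'
#' @param results stacked [epoch_regression()] rows across neurons, with a
#'   `region` column.
#' @param alpha per-test criterion.
#' @param n_comparisons Bonferroni denominator.
#' @return data.frame with `region`, `epoch`, `category`, `n`, `n_sig`,
#'   `fraction`, `chance`, `p_vs_chance`, `sig_vs_chance`, and (when both
#'   regions are present) `p_region_diff`, `sig_region_diff` per
#'   epoch x category.
#' @export
population_fractions <- function(results, alpha = 0.05,
                                 n_comparisons = 72L) {
  if (!"region" %in% names(results))
    stop("results must carry a region column")
  pools <- list(
    choice = "choice", reward_context = "reward_context",
    reward_size = "reward_size",
    coh_either = c("coh_contra", "coh_ipsi"),
    rewcoh_either = c("rewcoh_contra", "rewcoh_ipsi"),
    rt_either = c("rt_contra", "rt_ipsi"),
    rewrt_either = c("rewrt_contra", "rewrt_ipsi"))
  present <- vapply(pools, function(p)
    any(p %in% results$regressor), logical(1))
  pools <- pools[present]
  rows <- list()
  for (reg in unique(results$region)) {
    for (e in sort(unique(results$epoch))) {
      sub <- results[results$region == reg & results$epoch == e, ]
      for (cat in names(pools)) {
        members <- pools[[cat]]
        per_neuron <- tapply(
          sub$p[sub$regressor %in% members] < alpha,
          sub$neuron_id[sub$regressor %in% members],
          function(x) any(x, na.rm = TRUE))
        n <- length(per_neuron)
        if (n == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            region = reg, epoch = e, category = cat, n = 0L,
            n_sig = NA_integer_, fraction = NA_real_,
            chance = 1 - (1 - alpha)^length(members),
            p_vs_chance = NA_real_, sig_vs_chance = NA)
          next
        }
        k <- sum(per_neuron)
        chance <- 1 - (1 - alpha)^length(members)
        pv <- suppressWarnings(
          chisq.test(c(k, n - k), p = c(chance, 1 - chance))$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, epoch = e, category = cat, n = n, n_sig = k,
          fraction = k / n, chance = chance, p_vs_chance = pv,
          sig_vs_chance = pv < alpha / n_comparisons)
      }
    }
  }
  out <- do.call(rbind, rows)
  regions <- unique(out$region)
  if (length(regions) == 2L) {
    out$p_region_diff <- NA_real_
    out$sig_region_diff <- NA
    for (e in unique(out$epoch)) for (cat in unique(out$category)) {
      i1 <- which(out$epoch == e & out$category == cat &
                    out$region == regions[1])
      i2 <- which(out$epoch == e & out$category == cat &
                    out$region == regions[2])
      if (!length(i1) || !length(i2)) next
      a <- out[i1, ]; b <- out[i2, ]
      if (is.na(a$fraction) || is.na(b$fraction)) next
      m <- matrix(c(a$n_sig, a$n - a$n_sig, b$n_sig, b$n - b$n_sig), 2)
      pv <- suppressWarnings(chisq.test(m)$p.value)
      out$p_region_diff[c(i1, i2)] <- pv
      out$sig_region_diff[c(i1, i2)] <- pv < alpha / n_comparisons
    }
  }
  out
}
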