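#' Condition-averaged smoothed firing rates
#'
#' Computes, over correct trials, the trial-averaged firing rate of each
#' coherence-magnitude x reward-context condition on a 1 ms grid, convolved
#' with a Gaussian kernel (default sigma 20 ms, kernel renormalised at the
#' edges), and truncated at the condition's median RT: motion-aligned curves
#' cover `[0, median RT)`, saccade-aligned curves `(-median RT, 0]`.
#' Reward context is expressed in the neuron's preferred-choice frame
#' (+1 = preferred choice paired with the large reward).
#'
#' @param recording a [neuron_recording()] with a defined
#'   `preferred_choice` (or pass `choice = "all"`).
#' @param alignment `"motion"` or `"saccade"`.
#' @param choice which trials: `"preferred"`, `"null"` or `"all"`.
#' @param sigma Gaussian smoothing SD (s).
#' @return object of class `psth_set`: list of conditions, each with
#'   `coherence` (unsigned), `context` (+1/-1, preferred frame), `n_trials`,
#'   `median_rt`, `time`, `rate`. Empty conditions are omitted with a
#'   message.
#' @export
condition_psth <- function(recording, alignment = c("motion", "saccade"),
                           choice = c("preferred", "null", "all"),
                           sigma = 0.020) {
  alignment <- match.arg(alignment)
  choice <- match.arg(choice)
  stopifnot(inherits(recording, "neuron_recording"))
  trials <- recording$trials
  pref_code <- switch(recording$preferred_choice, reference = 1L, other = -1L,
                      undefined = NA_integer_)
  if (choice != "all" && is.na(pref_code))
    stop("preferred choice undefined; use choice = \"all\"")
  keep <- trials$correct == 1
  if (choice == "preferred") keep <- keep & trials$choice == pref_code
  if (choice == "null") keep <- keep & trials$choice == -pref_code
  idx <- which(keep)
  if (!length(idx)) stop("no qualifying correct trials")
  ctx <- if (is.na(pref_code)) trials$reward_context else
    pref_code * trials$reward_context
  mag <- abs(trials$signed_coherence)
  ev <- if (alignment == "motion") trials$t_motion_on_s else
    trials$t_saccade_on_s

  conds <- unique(data.frame(coherence = mag[idx], context = ctx[idx]))
  conds <- conds[order(conds$coherence, conds$context), ]
  out <- list()
  for (r in seq_len(nrow(conds))) {
    ci <- idx[mag[idx] == conds$coherence[r] & ctx[idx] == conds$context[r]]
    med_rt <- median(trials$rt_s[ci])
    grid <- if (alignment == "motion")
      seq(0, med_rt - 0.001, by = 0.001) else
        seq(-med_rt + 0.001, 0, by = 0.001)
    rel <- unlist(lapply(ci, function(i) recording$spikes[[i]] - ev[i]))
    t0g <- grid[1] - 0.0005
    bin_idx <- floor((rel - t0g) / 0.001) + 1L
    bin_idx <- bin_idx[bin_idx >= 1L & bin_idx <= length(grid)]
    counts <- tabulate(bin_idx, nbins = length(grid))
    rate <- gauss_smooth(counts / length(ci) / 0.001, sigma, 0.001)
    out[[length(out) + 1L]] <- list(coherence = conds$coherence[r],
                                    context = conds$context[r],
                                    n_trials = length(ci),
                                    median_rt = med_rt,
                                    time = grid, rate = rate)
  }
  structure(list(conditions = out, alignment = alignment, choice = choice,
                 neuron_id = recording$neuron_id), class = "psth_set")
}

# Gaussian smoothing with kernel renormalisation at the edges, so flat
# inputs stay flat near the boundaries.
gauss_smooth <- function(x, sigma, dt) {
  if (sigma <= 0) return(x)
  half <- ceiling(4 * sigma / dt)
  k <- dnorm(seq(-half, half) * dt, sd = sigma)
  n <- length(x)
  padded <- c(rep(0, half), x, rep(0, half))
  num <- as.numeric(stats::filter(padded, k / sum(k), sides = 2))[
    (half + 1):(half + n)]
  ind <- c(rep(0, half), rep(1, n), rep(0, half))
  den <- as.numeric(stats::filter(ind, k / sum(k), sides = 2))[
    (half + 1):(half + n)]
  num / den
}

#' Slope of firing-rate change in running windows
#'
#' Least-squares slope of rate against time within 200 ms windows stepped
#' every 20 ms along a smoothed rate curve. Windows extending beyond the
#' curve are omitted.
#'
#' @param time,rate the curve (uniform 1 ms grid).
#' @param window window width (s).
#' @param step window step (s).
#' @return data.frame with `center` (s) and `slope` (spikes/s per s).
#' @export
slope_timeseries <- function(time, rate, window = 0.2, step = 0.02) {
  if (length(time) < 2L || diff(range(time)) < window)
    return(data.frame(center = numeric(0), slope = numeric(0)))
  centers <- seq(min(time) + window / 2, max(time) - window / 2 + 1e-9,
                 by = step)
  slope <- vapply(centers, function(ct) {
    i <- which(time >= ct - window / 2 & time <= ct + window / 2)
    tv <- time[i]
    rv <- rate[i]
    ok <- is.finite(rv)
    if (sum(ok) < 2L) return(NA_real_)
    tv <- tv[ok]; rv <- rv[ok]
    sum((tv - mean(tv)) * (rv - mean(rv))) / sum((tv - mean(tv))^2)
  }, numeric(1))
  data.frame(center = centers, slope = slope)
}

#' Modulation of firing-rate slopes by coherence and reward context
#'
#' Multiple linear regression of condition-level slopes on coherence
#' (unsigned), reward context (+1/-1) and their interaction, with t-test
#' p-values per coefficient.
#'
#' @param slopes data.frame with columns `coherence`, `context`, `slope`
#'   (one row per condition).
#' @return data.frame with rows `intercept`, `coherence`, `context`,
#'   `interaction`: `beta`, `se`, `p`.
#' @export
slope_modulation_regression <- function(slopes) {
  if (length(unique(slopes$coherence)) < 2L)
    stop("need >= 2 coherence levels")
  one_ctx <- length(unique(slopes$context)) < 2L
  if (one_ctx) {
    warning("single reward context: context terms aliased and dropped")
    fit <- lm(slope ~ coherence, data = slopes)
  } else {
    fit <- lm(slope ~ coherence * context, data = slopes)
  }
  co <- coef(summary(fit))
  map <- c("(Intercept)" = "intercept", coherence = "coherence",
           context = "context", "coherence:context" = "interaction")
  out <- data.frame(regressor = unname(map[rownames(co)]), beta = co[, 1],
                    se = co[, 2], p = co[, 4], row.names = NULL)
  out$p[is.nan(out$p)] <- 1
  out
}

#' Slope-modulation time series for one neuron
#'
#' Full per-neuron slope pipeline: condition PSTHs ([condition_psth()]),
#' per-condition slope time series ([slope_timeseries()]), then for every
#' window center shared by at least two coherence levels in both contexts,
#' the condition-level modulation regression
#' ([slope_modulation_regression()]).
#'
#' @inheritParams condition_psth
#' @param window,step slope window width and step (s).
#' @return data.frame of class `slope_series`: per window `center`,
#'   `beta_coh`, `p_coh`, `beta_ctx`, `p_ctx`, `beta_int`, `p_int`,
#'   `n_conditions`.
#' @export
slope_series <- function(recording, alignment = c("motion", "saccade"),
                         choice = c("preferred", "null", "all"),
                         sigma = 0.020, window = 0.2, step = 0.02) {
  alignment <- match.arg(alignment)
  choice <- match.arg(choice)
  ps <- condition_psth(recording, alignment, choice, sigma)
  tabs <- lapply(ps$conditions, function(cn) {
    st <- slope_timeseries(cn$time, cn$rate, window, step)
    if (!nrow(st)) return(NULL)
    st$coherence <- cn$coherence
    st$context <- cn$context
    st
  })
  tabs <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  if (is.null(tabs) || !nrow(tabs))
    return(structure(data.frame(), class = c("slope_series", "data.frame")))
  # snap centers onto a common lattice
  tabs$center <- round(tabs$center / step) * step
  n_cond <- length(ps$conditions)
  rows <- list()
  for (ct in sort(unique(tabs$center))) {
    sub <- tabs[tabs$center == ct & is.finite(tabs$slope), ]
    # modulation coefficients are only comparable across windows estimated
    # from the same condition set: windows past a condition's truncation
    # point are dropped
    if (nrow(sub) < n_cond) next
    if (length(unique(sub$coherence)) < 2L ||
        length(unique(sub$context)) < 2L) next
    mr <- slope_modulation_regression(sub)
    g <- function(term, col) {
      v <- mr[[col]][mr$regressor == term]
      if (length(v)) v else NA_real_
    }
    rows[[length(rows) + 1L]] <- data.frame(
      center = ct,
      beta_coh = g("coherence", "beta"), p_coh = g("coherence", "p"),
      beta_ctx = g("context", "beta"), p_ctx = g("context", "p"),
      beta_int = g("interaction", "beta"), p_int = g("interaction", "p"),
      n_conditions = nrow(sub))
  }
  out <- do.call(rbind, rows)
  out$alignment <- alignment
  out$neuron_id <- recording$neuron_id
  class(out) <- c("slope_series", "data.frame")
  out
}

#' Peak coherence-modulation window and context/coherence ratio
#'
#' Among windows with a significant coherence coefficient (restricted to
#' centers at or after +0.1 s for motion-aligned series, imposing a minimum
#' visual latency), selects the window with the largest absolute coherence
#' coefficient and returns the ratio of the reward-context to the coherence
#' coefficient there. Neurons with no significant coherence window are
#' flagged ineligible.
#'
#' @param series a [slope_series()] result.
#' @param alpha significance criterion for the coherence coefficient.
#' @param min_latency minimum window center (s) for motion alignment.
#' @return list with `eligible`, and when eligible `center`, `beta_coh`,
#'   `beta_ctx`, `beta_int`, `ratio`.
#' @export
peak_window_ratio <- function(series, alpha = 0.05, min_latency = 0.1) {
  if (!nrow(series)) return(list(eligible = FALSE))
  cand <- series[is.finite(series$p_coh) & series$p_coh < alpha, ]
  if (identical(series$alignment[1], "motion"))
    cand <- cand[cand$center >= min_latency, ]
  if (!nrow(cand)) return(list(eligible = FALSE))
  i <- which.max(abs(cand$beta_coh))
  list(eligible = TRUE, center = cand$center[i],
       beta_coh = cand$beta_coh[i], beta_ctx = cand$beta_ctx[i],
       beta_int = cand$beta_int[i],
       ratio = cand$beta_ctx[i] / cand$beta_coh[i])
}

#' Correlation between neural modulation ratios and behavioural drift bias
#'
#' Pearson correlation (two-sided t-test) between per-neuron
#' reward-context:coherence slope-modulation ratios and the per-session
#' behavioural drift-rate bias, plus the least-squares line.
#'
#' @param ratios per-neuron ratio values.
#' @param biases matching per-session `delta_drift` values.
#' @return list with `r`, `p`, `n`, `intercept`, `slope`.
#' @export
ratio_bias_correlation <- function(ratios, biases) {
  ok <- is.finite(ratios) & is.finite(biases)
  ratios <- ratios[ok]; biases <- biases[ok]
  if (length(ratios) < 3L) stop("need at least 3 paired observations")
  if (sd(ratios) == 0 || sd(biases) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(ratios),
                intercept = NA_real_, slope = NA_real_))
  }
  ct <- cor.test(ratios, biases)
  fit <- lm(biases ~ ratios)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ratios),
       intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

#' Per-neuron slope summary table
#'
#' One row per neuron in the layout of the deposited per-neuron source
#' tables, ready for [ratio_bias_correlation()]:
#' `neuron_id, alignment, peak_window_s, beta_coh, beta_context,
#' beta_interaction, ratio, eligible`.
#'
#' @param series_list list of [slope_series()] results.
#' @param ... passed to [peak_window_ratio()].
#' @return data.frame.
#' @export
slope_summary_table <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    pk <- peak_window_ratio(s, ...)
    data.frame(
      neuron_id = if (nrow(s)) s$neuron_id[1] else NA_character_,
      alignment = if (nrow(s)) s$alignment[1] else NA_character_,
      peak_window_s = if (pk$eligible) pk$center else NA_real_,
      beta_coh = if (pk$eligible) pk$beta_coh else NA_real_,
      beta_context = if (pk$eligible) pk$beta_ctx else NA_real_,
      beta_interaction = if (pk$eligible) pk$beta_int else NA_real_,
      ratio = if (pk$eligible) pk$ratio else NA_real_,
      eligible = pk$eligible)
  })
  do.call(rbind, rows)
}

#' Read a per-neuron slope source-data table
#'
#' Ingestion adapter for per-neuron CSV tables in the
#' [slope_summary_table()] layout augmented with a `delta_drift` column, so
#' deposited per-neuron tables can feed [ratio_bias_correlation()] directly.
#'
#' @param path CSV path.
#' @return list with the table (`table`) and the correlation result
#'   (`correlation`) over eligible rows.
#' @export
read_slope_source_data <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ratio", "delta_drift")
  if (!all(need %in% names(tab)))
    stop("source table needs columns: ", paste(need, collapse = ", "))
  ok <- if ("eligible" %in% names(tab)) as.logical(tab$eligible) else
    rep(TRUE, nrow(tab))
  list(table = tab,
       correlation = ratio_bias_correlation(tab$ratio[ok],
                                            tab$delta_drift[ok]))
}
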