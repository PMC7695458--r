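TRIAL_TABLE_COLS <- c("session_id", "trial_index", "reward_context",
                      "signed_coherence", "choice", "correct", "rt_s",
                      "t_target_on_s", "t_motion_on_s", "t_saccade_on_s")

#' Validate a trial table
#'
#' Checks the per-trial behavioural schema: one row per trial with columns
#' `session_id`, `trial_index`, `reward_context` (+1 reference-large /
#' -1 reference-small), `signed_coherence` (fraction, positive toward the
#' reference choice), `choice` (+1 reference / -1 other), `correct` (0/1),
#' `rt_s` and the three event times `t_target_on_s < t_motion_on_s <
#' t_saccade_on_s` on the session clock. `rt_s` must equal
#' `t_saccade_on_s - t_motion_on_s` within 1 ms.
#'
#' @param trials data.frame.
#' @param check_blocks also require reward contexts to occur in contiguous
#'   alternating blocks.
#' @return the validated data.frame (invisibly usable), or an error naming
#'   the first violated rule.
#' @export
validate_trial_table <- function(trials, check_blocks = FALSE) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("trial table must be a non-empty data.frame")
  missing_cols <- setdiff(TRIAL_TABLE_COLS, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(trials$reward_context %in% c(1, -1)))
    stop("reward_context must be coded +1/-1")
  if (!all(trials$choice %in% c(1, -1)))
    stop("choice must be coded +1/-1")
  if (!all(trials$correct %in% c(0, 1)))
    stop("correct must be coded 0/1")
  bad_rt <- abs(trials$rt_s - (trials$t_saccade_on_s - trials$t_motion_on_s)) > 1e-3
  if (any(bad_rt))
    stop("rt_s must equal t_saccade_on_s - t_motion_on_s within 1 ms (first bad row: ",
         which(bad_rt)[1], ")")
  if (any(trials$t_target_on_s >= trials$t_motion_on_s) ||
      any(trials$t_motion_on_s >= trials$t_saccade_on_s))
    stop("event times must satisfy target < motion < saccade per trial")
  if (check_blocks) {
    r <- rle(trials$reward_context)
    if (length(r$values) > 1 && any(diff(r$values) == 0))
      stop("reward contexts must alternate in contiguous blocks")
  }
  trials
}

#' Read / write trial tables as CSV
#'
#' Delimited-text schema: one row per trial, columns exactly
#' `session_id, trial_index, reward_context, signed_coherence, choice,
#' correct, rt_s, t_target_on_s, t_motion_on_s, t_saccade_on_s`.
#'
#' @param path CSV file path.
#' @param trials trial table to write.
#' @return `read_trial_table` returns the validated data.frame.
#' @export
read_trial_table <- function(path) {
  validate_trial_table(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  write.csv(trials[TRIAL_TABLE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Construct a neuron recording
#'
#' Bundles per-trial spike times with the session's trial table and neuron
#' metadata. Spike times are on the session clock; every spike must fall
#' within its trial's recording span (taken as
#' `[t_target_on_s - 0.5, t_saccade_on_s + 0.8]`).
#'
#' @param neuron_id label.
#' @param spikes list of numeric vectors of spike times (s), one element per
#'   row of `trials`, in trial order.
#' @param trials trial table for the session.
#' @param region `"FEF"` or `"caudate"`.
#' @param monkey subject label.
#' @param motion_axis `"horizontal"` or `"vertical"`.
#' @param preferred_choice `"reference"`, `"other"` or `"undefined"`.
#' @param ground_truth optional list with the generative encoding parameters
#'   (kept by the synthetic generator for recovery tests).
#' @return object of class `neuron_recording`.
#' @export
neuron_recording <- function(neuron_id, spikes, trials, region = "FEF",
                             monkey = "synthetic", motion_axis = "horizontal",
                             preferred_choice = "undefined",
                             ground_truth = NULL) {
  trials <- validate_trial_table(trials)
  if (length(spikes) != nrow(trials))
    stop("spikes must have one element per trial")
  lo <- trials$t_target_on_s - 0.5
  hi <- trials$t_saccade_on_s + 0.8
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s) && (any(s < lo[i]) || any(s > hi[i])))
      stop("spike times outside the recording span of trial ", i)
  }
  structure(list(neuron_id = neuron_id, spikes = spikes, trials = trials,
                 region = match.arg(region, c("FEF", "caudate")),
                 monkey = monkey,
                 motion_axis = match.arg(motion_axis,
                                         c("horizontal", "vertical")),
                 preferred_choice = match.arg(preferred_choice,
                                              c("reference", "other",
                                                "undefined")),
                 ground_truth = ground_truth),
            class = "neuron_recording")
}

#' @export
print.neuron_recording <- function(x, ...) {
  cat(sprintf("Neuron %s (%s, monkey %s): %d trials, %d spikes, preferred = %s\n",
              x$neuron_id, x$region, x$monkey, nrow(x$trials),
              sum(lengths(x$spikes)), x$preferred_choice))
  invisible(x)
}

#' Read / write spike trains as JSON lines
#'
#' One structured-text file per neuron: the first line is a header record
#' with the neuron metadata (`neuron_id`, `region`, `monkey`, `motion_axis`,
#' `preferred_choice`), each following line is
#' `{"trial_index": i, "spike_times_s": [...]}`.
#'
#' @param recording a [neuron_recording()].
#' @param path file path.
#' @param trials the session trial table (spike files do not duplicate it).
#' @return `read_spike_trains` returns a `neuron_recording`.
#' @export
write_spike_trains <- function(recording, path) {
  stopifnot(inherits(recording, "neuron_recording"))
  hdr <- jsonlite::toJSON(list(neuron_id = recording$neuron_id,
                               region = recording$region,
                               monkey = recording$monkey,
                               motion_axis = recording$motion_axis,
                               preferred_choice = recording$preferred_choice),
                          auto_unbox = TRUE, digits = NA)
  lines <- vapply(seq_along(recording$spikes), function(i) {
    jsonlite::toJSON(list(trial_index = recording$trials$trial_index[i],
                          spike_times_s = as.numeric(recording$spikes[[i]])),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, trials) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  idx <- vapply(recs, `[[`, numeric(1), "trial_index")
  ord <- match(trials$trial_index, idx)
  if (any(is.na(ord)))
    stop("spike file lacks trials present in the trial table")
  spikes <- lapply(recs[ord], function(r) as.numeric(r$spike_times_s))
  neuron_recording(hdr$neuron_id, spikes, trials, region = hdr$region,
                   monkey = hdr$monkey, motion_axis = hdr$motion_axis,
                   preferred_choice = hdr$preferred_choice)
}

#' Write a DDM fit as JSON
#'
#' Parameter names follow [ddm_params()]; the per-run log posterior scores
#' are included.
#'
#' @param fit a `ddm_fit`.
#' @param path file path.
#' @export
write_ddm_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ddm_fit"))
  p <- fit$params
  jsonlite::write_json(list(
    k = p$k, me_by_context = as.list(p$me_by_context),
    z_by_context = as.list(p$z_by_context), a = p$a,
    beta_alpha = p$beta_alpha, beta_d = p$beta_d, t0 = p$t0,
    log_posterior = fit$log_posterior, loglik = fit$loglik,
    per_run_log = fit$per_run_log, se = as.list(fit$se),
    n_trials = fit$n_trials), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
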