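EPOCH_NAMES <- c("target_400", "target_to_motion", "pre_motion_400",
                 "motion_to_median_rt", "motion_to_saccade", "pre_saccade_100",
                 "peri_saccade_300", "post_saccade_400")

#' Task epochs for spike-count regressions
#'
#' Builds the eight per-trial analysis windows from the trial event times
#' (`T` target onset, `M` motion onset, `S` saccade onset), all half-open
#' `[start, end)` in seconds on the session clock:
#' 1 `[T, T+0.4)`, 2 `[T, M)`, 3 `[M-0.4, M)`, 4 `[M+0.1, M+median_rt-0.1)`,
#' 5 `[M+0.1, S-0.1)`, 6 `[S-0.1, S)`, 7 `[S-0.1, S+0.2)`, 8 `[S, S+0.4)`.
#' Epoch 4 uses the session's median RT; variable-length epochs (2, 4, 5)
#' can be degenerate (non-positive duration) for fast trials — they are
#' flagged, never silently dropped.
#'
#' @param events trial table (or any data.frame with `t_target_on_s`,
#'   `t_motion_on_s`, `t_saccade_on_s`).
#' @param median_rt session median RT (s); defaults to the median of
#'   `rt_s` over correct trials when the column is present.
#' @return object of class `epoch_set`: list with `start`, `end` (n x 8
#'   matrices), `degenerate` (logical matrix) and `median_rt`.
#' @export
define_epochs <- function(events, median_rt = NULL) {
  Tt <- events$t_target_on_s
  M <- events$t_motion_on_s
  S <- events$t_saccade_on_s
  if (any(Tt >= M) || any(M >= S))
    stop("event times must satisfy target < motion < saccade per trial")
  if (is.null(median_rt)) {
    if (!"rt_s" %in% names(events))
      stop("median_rt must be given when events lack an rt_s column")
    keep <- if ("correct" %in% names(events)) events$correct == 1 else TRUE
    median_rt <- median(events$rt_s[keep])
  }
  start <- cbind(Tt, Tt, M - 0.4, M + 0.1, M + 0.1, S - 0.1, S - 0.1, S)
  end <- cbind(Tt + 0.4, M, M, M + median_rt - 0.1, S - 0.1, S, S + 0.2,
               S + 0.4)
  colnames(start) <- colnames(end) <- EPOCH_NAMES
  structure(list(start = start, end = end, degenerate = end <= start,
                 median_rt = median_rt),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x 8 epochs (median RT %.3f s)\n",
              nrow(x$start), x$median_rt))
  deg <- colSums(x$degenerate)
  if (any(deg > 0))
    cat("  degenerate windows:",
        paste(sprintf("#%d x%d", which(deg > 0), deg[deg > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

# spike counts within [start, end) per trial for one epoch column
epoch_spike_counts <- function(spikes, start, end) {
  vapply(seq_along(spikes), function(i) {
    s <- spikes[[i]]
    sum(s >= start[i] & s < end[i])
  }, numeric(1))
}
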