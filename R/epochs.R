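## Conventional ERP construction: fixed-window epochs with baseline
## correction, peak-to-peak / step rejection, and condition averages.
## Also extracts the variable-duration cue-to-response epochs used by the
## scaling-index analysis.

#' Epoch a continuous recording around events
#'
#' @param recording a [continuous_recording()].
#' @param events event table; rows of type `type` are epoched.
#' @param type event type to lock to.
#' @param window `c(pre_ms, post_ms)` half-open window around each event.
#' @param baseline_mode `"pre_event"` (mean over `[pre_ms, 0)`),
#'   `"around_event"` (mean over `[-20, 20)` ms) or `"none"`.
#' @return an `epoch_set`: `data` (trials x channels x time array, in
#'   microvolts), `window`, `times_ms`, `trial_meta` (`trial_id`,
#'   `condition`, `response_time_s`, `kept`); truncated epochs are dropped
#'   with a message.
#' @export
epoch_recording <- function(recording, events, type = "cue",
                            window = c(-200, 800),
                            baseline_mode = c("pre_event", "around_event", "none")) {
  stopifnot(inherits(recording, "continuous_recording"))
  baseline_mode <- match.arg(baseline_mode)
  fs <- recording$fs
  ev <- events[events$type == type, , drop = FALSE]
  n_time <- window_n_samples(window[1], window[2], fs)
  offsets <- as.integer(round(window[1] * fs / 1000)) + seq_len(n_time) - 1L
  n_samples <- ncol(recording$data)
  n_ch <- nrow(recording$data)

  keep_ev <- (ev$sample + offsets[1] >= 0L) &
             (ev$sample + offsets[n_time] < n_samples)
  if (any(!keep_ev))
    message(sum(!keep_ev), " truncated epoch(s) dropped at the recording edge")
  ev <- ev[keep_ev, , drop = FALSE]

  data <- array(0, dim = c(nrow(ev), n_ch, n_time))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$sample[i] + offsets + 1L
    data[i, , ] <- recording$data[, idx, drop = FALSE]
  }
  times_ms <- window[1] + (seq_len(n_time) - 1L) * 1000 / fs
  bl_idx <- switch(baseline_mode,
                   pre_event = which(times_ms < 0),
                   around_event = which(times_ms >= -20 & times_ms < 20),
                   none = integer(0))
  if (length(bl_idx) > 0) {
    for (i in seq_len(nrow(ev))) {
      bl <- apply(data[i, , bl_idx, drop = FALSE], 2, mean)  # per-channel mean
      data[i, , ] <- data[i, , ] - bl
    }
  }
  structure(list(data = data, window = window, times_ms = times_ms,
                 baseline_mode = baseline_mode,
                 channel_labels = recording$channel_labels,
                 trial_meta = data.frame(trial_id = ev$trial_id,
                                         condition = ev$condition,
                                         response_time_s = ev$response_time_s,
                                         kept = TRUE,
                                         stringsAsFactors = FALSE)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d channels x %d timepoints, window [%g, %g) ms\n",
              dim(x$data)[1], sum(x$trial_meta$kept), dim(x$data)[2],
              dim(x$data)[3], x$window[1], x$window[2]))
  invisible(x)
}

#' Threshold-based epoch rejection
#'
#' A trial is marked not kept if on any channel the sample-to-sample
#' voltage step exceeds `step_uv` or the total range (max minus min) over
#' the epoch exceeds `range_uv`.  Rejected trials retain their metadata.
#'
#' @param epochs an `epoch_set`.
#' @param step_uv consecutive-sample step threshold (default 50).
#' @param range_uv whole-epoch range threshold (default 150).
#' @export
reject_epochs <- function(epochs, step_uv = 50, range_uv = 150) {
  check_scalar_number(step_uv, "step_uv", positive = TRUE)
  check_scalar_number(range_uv, "range_uv", positive = TRUE)
  for (i in seq_len(dim(epochs$data)[1])) {
    m <- epochs$data[i, , , drop = FALSE][1, , ]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    step <- if (ncol(m) > 1) max(abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])) else 0
    rng <- max(apply(m, 1, function(x) max(x) - min(x)))
    if (step > step_uv || rng > range_uv) epochs$trial_meta$kept[i] <- FALSE
  }
  epochs
}

#' Condition-average ERPs
#'
#' Arithmetic mean over kept trials, per condition.
#'
#' @param epochs an `epoch_set`.
#' @param by condition labels to average (default: all present).
#' @return named list of `erp_average`s (`mean`: channels x time matrix,
#'   `n_trials`, `condition`, `times_ms`); conditions with zero kept trials
#'   are omitted with a warning.
#' @export
average_epochs <- function(epochs, by = unique(epochs$trial_meta$condition)) {
  out <- list()
  for (cond in by) {
    sel <- which(epochs$trial_meta$kept & epochs$trial_meta$condition == cond)
    if (length(sel) == 0L) {
      warning("condition '", cond, "' has no kept trials; omitted", call. = FALSE)
      next
    }
    m <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs$channel_labels
    out[[cond]] <- structure(list(mean = m, n_trials = length(sel),
                                  condition = cond, times_ms = epochs$times_ms),
                             class = "erp_average")
  }
  out
}

#' Variable-duration interval epochs
#'
#' Extracts each trial's start-to-end interval (e.g. cue to response) as a
#' ragged list of channels x duration matrices, the raw material for the
#' scaling-index analysis.
#'
#' @param recording a [continuous_recording()].
#' @param events paired event table.
#' @param start_event,end_event delimiting event types.
#' @return list with `epochs` (per-trial matrices), `meta` (`trial_id`,
#'   `condition`, `duration_samples`).
#' @export
interval_epochs <- function(recording, events, start_event = "cue",
                            end_event = "response") {
  trials <- split(events, events$trial_id)
  eps <- list(); meta <- list()
  for (tr in trials) {
    s <- tr$sample[tr$type == start_event]
    e <- tr$sample[tr$type == end_event]
    if (length(s) != 1L || length(e) != 1L || e <= s) next
    idx <- (s + 1L):e
    eps[[length(eps) + 1L]] <- recording$data[, idx, drop = FALSE]
    meta[[length(meta) + 1L]] <- data.frame(trial_id = tr$trial_id[1],
                                            condition = tr$condition[1],
                                            duration_samples = e - s,
                                            stringsAsFactors = FALSE)
  }
  list(epochs = eps, meta = do.call(rbind, meta))
}
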