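## Convolutional design matrices: fixed-time stick-function blocks, the
## variable-duration scaled-time block, and sample-exclusion machinery.
## Sample indices are 0-based throughout; fixed windows are half-open
## [pre_ms, post_ms) so a 1,000 ms window at 200 Hz is exactly 200 columns.

#' Continuous multichannel recording
#'
#' @param data channels x samples amplitude matrix in microvolts.
#' @param fs sampling rate (Hz).
#' @param channel_labels unique channel names (defaults to CH01, CH02, ...).
#' @return a `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  check_scalar_number(fs, "fs", positive = TRUE)
  if (!all(is.finite(data))) stop_invalid("recording contains non-finite values")
  if (is.null(channel_labels)) channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  if (anyDuplicated(channel_labels) || length(channel_labels) != nrow(data))
    stop_invalid("channel labels must be unique, one per row")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Fixed-time window specification
#' @param component component name attached to the design columns.
#' @param pre_ms,post_ms window bounds relative to the event in ms,
#'   half-open `[pre_ms, post_ms)`.
#' @export
fixed_window <- function(component, pre_ms, post_ms) {
  if (post_ms <= pre_ms) stop_invalid("post_ms must exceed pre_ms")
  structure(list(component = component, pre_ms = pre_ms, post_ms = post_ms),
            class = "fixed_window")
}

#' Scaled-time specification
#' @param n_points number of scaled-time basis points (>= 2).
#' @param start_event,end_event event types delimiting the interval.
#' @export
scaled_spec <- function(n_points = 330, start_event = "cue",
                        end_event = "response") {
  n_points <- check_count(n_points, "n_points", min = 2L)
  structure(list(n_points = n_points, start_event = start_event,
                 end_event = end_event), class = "scaled_spec")
}

design_block <- function(X, columns, edge_rows = integer(0)) {
  structure(list(X = X, columns = columns, edge_rows = edge_rows),
            class = "design_block")
}

#' Fixed-time stick-function block
#'
#' Column `j` of the block (lag `pre_ms + j * 1000/fs`) carries a 1 at
#' sample `event_sample + lag` for every event of the requested type;
#' overlapping events sum.  Entries that would fall outside the recording
#' are dropped and the affected samples flagged as `edge`.
#'
#' @param events event table (`data.frame` with `type` and 0-based `sample`).
#' @param window a [fixed_window()].
#' @param n_samples recording length in samples.
#' @param fs sampling rate (Hz).
#' @param type event type selected from `events` (defaults to the window's
#'   component name).
#' @return a `design_block`: sparse `n_samples x n_lags` matrix plus
#'   per-column metadata (`component`, `lag_ms`) and `edge_rows`.
#' @export
build_fixed_block <- function(events, window, n_samples, fs,
                              type = window$component) {
  n_samples <- check_count(n_samples, "n_samples")
  lags_ms <- window_lags_ms(window$pre_ms, window$post_ms, fs)
  lag_samp <- as.integer(round(lags_ms * fs / 1000))
  ev <- events$sample[events$type == type]

  i <- rep(ev, each = length(lag_samp)) + lag_samp   # 0-based rows
  j <- rep(seq_along(lag_samp), times = length(ev))
  ok <- i >= 0L & i < n_samples
  edge_rows <- integer(0)
  if (!all(ok)) {
    edge <- sort(unique(pmin(pmax(i[!ok], 0L), n_samples - 1L)))
    edge_rows <- edge + 1L
  }
  ## duplicated (row, col) pairs from coincident events sum automatically
  X <- Matrix::sparseMatrix(i = i[ok] + 1L, j = j[ok], x = 1,
                            dims = c(n_samples, length(lag_samp)))
  columns <- data.frame(component = window$component, lag_ms = lags_ms,
                        elapsed_fraction = NA_real_, stringsAsFactors = FALSE)
  design_block(X, columns, edge_rows)
}

#' Scaled-time block
#'
#' For each trial whose interval spans `D` samples, the rows
#' `[start, start + D)` receive `resize_box(n_points, D)`: one shared
#' basis of `n_points` columns whose temporal support stretches or
#' compresses per trial.  Columns therefore index elapsed fraction of the
#' interval, not wall-clock time.
#'
#' @param events event table with paired start/end events per `trial_id`.
#' @param spec a [scaled_spec()].
#' @param n_samples recording length in samples.
#' @return a `design_block` with `elapsed_fraction = (j - 0.5) / n_points`
#'   column metadata.
#' @export
build_scaled_block <- function(events, spec, n_samples) {
  n_samples <- check_count(n_samples, "n_samples")
  trials <- split(events, events$trial_id)
  ii <- list(); jj <- list(); xx <- list()
  for (tr in trials) {
    s <- tr$sample[tr$type == spec$start_event]
    e <- tr$sample[tr$type == spec$end_event]
    if (length(s) != 1L || length(e) != 1L)
      stop_invalid("trial %s lacks a unique %s/%s pair",
                   tr$trial_id[1], spec$start_event, spec$end_event)
    D <- e - s
    if (D < 2) stop_invalid("trial %s interval spans < 2 samples", tr$trial_id[1])
    R <- resize_box(spec$n_points, D)
    trip <- Matrix::summary(R)
    ii[[length(ii) + 1L]] <- s + trip$i         # 0-based start -> 1-based row
    jj[[length(jj) + 1L]] <- trip$j
    xx[[length(xx) + 1L]] <- trip$x
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_samples, spec$n_points))
  columns <- data.frame(component = "scaled", lag_ms = NA_real_,
                        elapsed_fraction = (seq_len(spec$n_points) - 0.5) / spec$n_points,
                        stringsAsFactors = FALSE)
  design_block(X, columns)
}

#' New all-keep sample mask
#' @param n_samples recording length.
#' @export
sample_mask <- function(n_samples) {
  structure(list(keep = rep(TRUE, n_samples),
                 reasons = rep(NA_character_, n_samples)),
            class = "sample_mask")
}

mask_flag <- function(mask, idx, reason) {
  idx <- idx[idx >= 1L & idx <= length(mask$keep)]
  mask$keep[idx] <- FALSE
  mask$reasons[idx] <- ifelse(is.na(mask$reasons[idx]), reason, mask$reasons[idx])
  mask
}

#' Flag continuous-artifact samples
#'
#' A moving window of `window_ms`, advancing by `step_ms`, flags all of its
#' samples when the peak-to-peak amplitude within the window exceeds
#' `threshold_uv` on any channel; the mask is shared across channels.
#'
#' @param recording a [continuous_recording()].
#' @param threshold_uv peak-to-peak threshold (microvolts), default 150.
#' @param window_ms,step_ms moving-window length and step, defaults
#'   2000 and 1000 ms.
#' @return a `sample_mask` with flagged samples labelled `"artifact"`.
#' @export
flag_artifact_samples <- function(recording, threshold_uv = 150,
                                  window_ms = 2000, step_ms = 1000) {
  stopifnot(inherits(recording, "continuous_recording"))
  n <- ncol(recording$data)
  if (n == 0L) stop_invalid("empty recording")
  if (step_ms <= 0 || window_ms < step_ms)
    stop_invalid("require window_ms >= step_ms > 0")
  wlen <- max(1L, as.integer(round(window_ms * recording$fs / 1000)))
  step <- max(1L, as.integer(round(step_ms * recording$fs / 1000)))
  mask <- sample_mask(n)
  starts <- seq(1L, n, by = step)
  for (s in starts) {
    idx <- s:min(s + wlen - 1L, n)
    seg <- recording$data[, idx, drop = FALSE]
    p2p <- apply(seg, 1L, function(x) max(x) - min(x))
    if (any(p2p > threshold_uv)) mask <- mask_flag(mask, idx, "artifact")
  }
  mask
}

#' Exclude trials with out-of-range response times
#'
#' Trials whose response time falls outside `[min_rt_s, max_rt_s]` have
#' their cue-to-response samples masked (`"bad_rt"`) and their events
#' removed.
#'
#' @param events event table.
#' @param mask a `sample_mask` to update.
#' @param min_rt_s,max_rt_s bounds in seconds (defaults 0.2 and 5).
#' @return list `events` (filtered) and `mask` (updated).
#' @export
exclude_response_trials <- function(events, mask, min_rt_s = 0.2, max_rt_s = 5) {
  if (min_rt_s >= max_rt_s) stop_invalid("min_rt_s must be < max_rt_s")
  rt <- tapply(events$response_time_s, events$trial_id, function(x) x[1])
  bad <- names(rt)[!is.na(rt) & (rt < min_rt_s | rt > max_rt_s)]
  for (tid in bad) {
    tr <- events[events$trial_id == tid, ]
    s <- min(tr$sample); e <- max(tr$sample)
    mask <- mask_flag(mask, (s + 1L):(e + 1L), "bad_rt")
  }
  list(events = events[!(events$trial_id %in% bad), , drop = FALSE], mask = mask)
}

#' Assemble the design matrix and apply the sample mask
#'
#' Concatenates blocks horizontally and removes masked rows from both the
#' design and every channel of the recording, keeping the surviving
#' original sample indices for audit.
#'
#' @param blocks list of `design_block`s sharing the recording's row count.
#' @param recording a [continuous_recording()].
#' @param mask a `sample_mask` (default: keep everything).
#' @param max_columns guard against runaway predictor counts.
#' @return a `rerp_design`: sparse `X`, column metadata, `row_index`
#'   (1-based surviving samples), masked `Y` (channels x kept samples),
#'   `fs`, `channel_labels`.
#' @export
assemble_design <- function(blocks, recording,
                            mask = sample_mask(ncol(recording$data)),
                            max_columns = 5000L) {
  n <- ncol(recording$data)
  for (b in blocks) {
    if (nrow(b$X) != n) stop_invalid("block row count differs from recording")
  }
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  columns <- do.call(rbind, lapply(blocks, `[[`, "columns"))
  if (ncol(X) > max_columns)
    stop_invalid("design has %d columns (> %d); use fewer points", ncol(X), max_columns)
  keep <- which(mask$keep)
  structure(list(X = X[keep, , drop = FALSE], columns = columns,
                 row_index = keep,
                 Y = recording$data[, keep, drop = FALSE],
                 fs = recording$fs,
                 channel_labels = recording$channel_labels),
            class = "rerp_design")
}

#' @export
print.rerp_design <- function(x, ...) {
  tab <- table(x$columns$component)
  cat(sprintf("<rerp_design> %d rows x %d predictors (%s); %d channels\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", "),
              length(x$channel_labels)))
  invisible(x)
}

#' Samples where any fixed-time regressor is active
#'
#' Used to restrict model-comparison errors to timepoints covered by the
#' fixed components (e.g. -200..800 ms around the cue).
#'
#' @param design a `rerp_design`.
#' @return logical vector over the design's retained rows.
#' @export
fixed_active_mask <- function(design) {
  fixed_cols <- which(design$columns$component != "scaled")
  if (length(fixed_cols) == 0L) stop_invalid("design has no fixed columns")
  Matrix::rowSums(abs(design$X[, fixed_cols, drop = FALSE])) > 0
}
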