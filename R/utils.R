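## Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (positive && x <= 0) stop_invalid("`%s` must be > 0", name)
  if (nonnegative && x < 0) stop_invalid("`%s` must be >= 0", name)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_scalar_number(x, name)
  if (x != round(x) || x < min)
    stop_invalid("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

## ms -> number of samples for a half-open window [pre, post)
window_n_samples <- function(pre_ms, post_ms, fs) {
  as.integer(round((post_ms - pre_ms) * fs / 1000))
}

## lag axis (ms) of a fixed window, one value per design column
window_lags_ms <- function(pre_ms, post_ms, fs) {
  n <- window_n_samples(pre_ms, post_ms, fs)
  pre_ms + (seq_len(n) - 1L) * 1000 / fs
}

## round-half-up, used to convert onsets in seconds to 0-based samples
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
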