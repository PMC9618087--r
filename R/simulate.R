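## Ground-truth simulator for interval-timing EEG: a fixed cue-locked
## transient, a fixed response-locked shape, and one scaled-time component
## stretched/compressed to fill each trial's cue-to-response interval,
## summed with noise on every channel.

#' Default component shapes
#'
#' Three smooth, visually distinct waveforms built from raised cosines:
#' a biphasic cue transient on (-200, 800) ms, a ramp-plus-peak
#' response-locked shape on (-800, 200) ms, and a slow negative half-cycle
#' as the scaled-time template on the unit interval.  All shapes are
#' zero-mean over their support (enforced) so baselines are unambiguous,
#' and amplitudes stay within +/- 20 microvolts.
#'
#' @param fs sampling rate in Hz.
#' @param n_scaled number of points in the scaled-time template.
#' @return named list of three `component_shape` objects
#'   (`cue`, `response`, `scaled`), each with fields `name`, `waveform`
#'   (microvolts) and `span` (`c(pre_ms, post_ms)` for fixed shapes,
#'   `NULL` for the scaled template).
#' @export
default_shapes <- function(fs = 200, n_scaled = 330) {
  check_scalar_number(fs, "fs", positive = TRUE)
  n_scaled <- check_count(n_scaled, "n_scaled", min = 2L)

  raised_cos <- function(t, center, width, amp) {
    u <- (t - center) / width
    ifelse(abs(u) < 0.5, amp * 0.5 * (1 + cos(2 * pi * u)), 0)
  }
  zero_mean <- function(x) x - mean(x)

  ## cue: positive peak ~150 ms then negative deflection ~420 ms
  t_cue <- window_lags_ms(-200, 800, fs)
  cue <- raised_cos(t_cue, 150, 220, 8) + raised_cos(t_cue, 420, 360, -6)

  ## response: slow negative ramp (half raised cosine) plus a sharp
  ## positive peak at the response
  t_resp <- window_lags_ms(-800, 200, fs)
  resp <- raised_cos(t_resp, 0, 1400, -7) + raised_cos(t_resp, 20, 180, 10)

  ## scaled template: slow negative half-cycle over elapsed fraction
  u <- (seq_len(n_scaled) - 0.5) / n_scaled
  scaled <- -9 * sin(pi * u)

  list(
    cue = component_shape("cue", zero_mean(cue), span = c(-200, 800)),
    response = component_shape("response", zero_mean(resp), span = c(-800, 200)),
    scaled = component_shape("scaled", zero_mean(scaled), span = NULL)
  )
}

component_shape <- function(name, waveform, span) {
  if (!all(is.finite(waveform)))
    stop_invalid("component waveform must be finite everywhere")
  structure(list(name = name, waveform = as.numeric(waveform), span = span),
            class = "component_shape")
}

#' Simulation configuration
#'
#' @param fs sampling rate (Hz).
#' @param interval_durations per-condition cue-to-response durations in
#'   seconds; the defaults mirror the short/medium/long production-task
#'   targets.
#' @param trials_per_condition trials simulated per condition.
#' @param inter_trial_gap `c(min_s, max_s)` of the uniform gap between one
#'   trial's response and the next trial's cue.
#' @param noise_model `"ar1"` or `"white"`.
#' @param noise_amplitude stationary noise RMS in microvolts.
#' @param ar_coef AR(1) coefficient (ignored for white noise).
#' @param jitter_sd per-trial Gaussian jitter of the interval duration in
#'   seconds, truncated at +/- 3 SD.
#' @param seed integer seed; every call with the same seed is bit-identical.
#' @return a `sim_config` list.
#' @export
sim_config <- function(fs = 200,
                       interval_durations = c(short = 0.8, medium = 1.65, long = 2.5),
                       trials_per_condition = 50,
                       inter_trial_gap = c(1.2, 2.0),
                       noise_model = c("ar1", "white"),
                       noise_amplitude = 5,
                       ar_coef = 0.95,
                       jitter_sd = 0.15,
                       seed = 1L) {
  check_scalar_number(fs, "fs", positive = TRUE)
  if (any(interval_durations <= 0)) stop_invalid("all interval durations must be > 0")
  trials_per_condition <- check_count(trials_per_condition, "trials_per_condition")
  if (length(inter_trial_gap) != 2L || any(inter_trial_gap < 0) ||
      inter_trial_gap[2] < inter_trial_gap[1])
    stop_invalid("inter_trial_gap must be c(min_s, max_s) with 0 <= min <= max")
  check_scalar_number(noise_amplitude, "noise_amplitude", nonnegative = TRUE)
  check_scalar_number(jitter_sd, "jitter_sd", nonnegative = TRUE)
  if (is.null(names(interval_durations)))
    names(interval_durations) <- paste0("cond", seq_along(interval_durations))
  structure(list(fs = fs,
                 interval_durations = interval_durations,
                 trials_per_condition = trials_per_condition,
                 inter_trial_gap = inter_trial_gap,
                 noise_model = match.arg(noise_model),
                 noise_amplitude = noise_amplitude,
                 ar_coef = ar_coef,
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## AR(1) noise with stationary SD `rms`; burn-in discards the transient.
ar1_noise <- function(n, phi, rms) {
  innov_sd <- rms * sqrt(1 - phi^2)
  burn <- 200L
  e <- stats::rnorm(n + burn, sd = innov_sd)
  x <- stats::filter(e, phi, method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

truncnorm <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, sd = sd)
  pmin(pmax(x, -3 * sd), 3 * sd)
}

#' Simulate a ground-truth interval-timing dataset
#'
#' Lays trials end to end: each trial inserts the cue shape at the cue
#' sample, the response shape at the response sample, and the scaled
#' template resampled with [resize_box()] to the trial's cue-to-response
#' duration.  Condition durations follow `config$interval_durations` with
#' truncated-Gaussian jitter; per-channel mixing weights give each
#' component a topography; noise is added per channel.
#'
#' @param config a [sim_config()].
#' @param shapes component set from [default_shapes()] (or compatible).
#' @param n_channels number of channels.
#' @param mixing optional `3 x n_channels` weight matrix (rows cue,
#'   response, scaled); by default drawn uniformly in `[0.6, 1.4]`.
#' @return a `scalerp_sim` list with fields `recording`
#'   ([continuous_recording()]), `events` (event table `data.frame`),
#'   `shapes`, `mixing`, `truth_contribution` (list of per-component
#'   channels x samples matrices) and `noise`; by construction
#'   `recording$data == Reduce("+", truth_contribution) + noise` exactly.
#' @export
simulate_dataset <- function(config, shapes = default_shapes(config$fs),
                             n_channels = 4, mixing = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_channels <- check_count(n_channels, "n_channels")
  fs <- config$fs
  set.seed(config$seed)

  n_pre_cue <- window_n_samples(shapes$cue$span[1], 0, fs)
  n_post_cue <- window_n_samples(0, shapes$cue$span[2], fs)
  n_pre_resp <- window_n_samples(shapes$response$span[1], 0, fs)
  n_post_resp <- window_n_samples(0, shapes$response$span[2], fs)

  conds <- names(config$interval_durations)
  condition <- sample(rep(conds, each = config$trials_per_condition))
  n_trials <- length(condition)

  durations <- config$interval_durations[condition] +
    truncnorm(n_trials, config$jitter_sd)
  d_samples <- as.integer(round(durations * fs))
  if (any(d_samples < 2))
    stop_invalid("simulated interval shorter than 2 samples; reduce jitter_sd")
  gaps <- stats::runif(n_trials, config$inter_trial_gap[1], config$inter_trial_gap[2])

  ## cue samples: leave room for the pre-cue window; gap runs response->cue
  cue <- integer(n_trials)
  cursor <- n_pre_cue + max(n_pre_resp - n_pre_cue, 0L) + 1L
  for (i in seq_len(n_trials)) {
    cue[i] <- cursor
    cursor <- cue[i] + d_samples[i] + as.integer(round(gaps[i] * fs))
  }
  resp <- cue + d_samples
  n_samples <- resp[n_trials] + n_post_resp + n_post_cue + as.integer(fs)

  if (is.null(mixing)) {
    mixing <- matrix(stats::runif(3 * n_channels, 0.6, 1.4), nrow = 3)
  }
  stopifnot(nrow(mixing) == 3, ncol(mixing) == n_channels)
  rownames(mixing) <- c("cue", "response", "scaled")

  add_events <- function(base, starts, wave) {
    ## accumulate a single-channel contribution series
    for (s in starts) {
      idx <- s + seq_along(wave) - 1L
      ok <- idx >= 1L & idx <= n_samples
      base[idx[ok]] <- base[idx[ok]] + wave[ok]
    }
    base
  }

  cue_series <- add_events(numeric(n_samples), cue - n_pre_cue, shapes$cue$waveform)
  resp_series <- add_events(numeric(n_samples), resp - n_pre_resp,
                            shapes$response$waveform)
  scaled_series <- numeric(n_samples)
  for (i in seq_len(n_trials)) {
    stretched <- as.numeric(resize_box(length(shapes$scaled$waveform),
                                       d_samples[i]) %*% shapes$scaled$waveform)
    idx <- cue[i] + seq_len(d_samples[i]) - 1L
    scaled_series[idx] <- scaled_series[idx] + stretched
  }

  contrib <- list(
    cue = outer(mixing["cue", ], cue_series),
    response = outer(mixing["response", ], resp_series),
    scaled = outer(mixing["scaled", ], scaled_series)
  )
  noise <- matrix(0, n_channels, n_samples)
  if (config$noise_amplitude > 0) {
    for (ch in seq_len(n_channels)) {
      noise[ch, ] <- if (config$noise_model == "ar1")
        ar1_noise(n_samples, config$ar_coef, config$noise_amplitude)
      else stats::rnorm(n_samples, sd = config$noise_amplitude)
    }
  }
  data <- contrib$cue + contrib$response + contrib$scaled + noise

  labels <- sprintf("CH%02d", seq_len(n_channels))
  recording <- continuous_recording(data, fs, labels)

  events <- data.frame(
    event_id = seq_len(2L * n_trials),
    type = rep(c("cue", "response"), n_trials),
    sample = as.integer(rbind(cue, resp)) - 1L,   # 0-based
    trial_id = rep(seq_len(n_trials), each = 2L),
    condition = rep(condition, each = 2L),
    response_time_s = rep(d_samples / fs, each = 2L),
    stringsAsFactors = FALSE
  )

  structure(list(recording = recording, events = events, shapes = shapes,
                 mixing = mixing, truth_contribution = contrib, noise = noise,
                 config = config),
            class = "scalerp_sim")
}

#' @export
print.scalerp_sim <- function(x, ...) {
  cat(sprintf("<scalerp_sim> %d channels x %d samples @ %g Hz, %d trials (%s)\n",
              nrow(x$recording$data), ncol(x$recording$data), x$recording$fs,
              max(x$events$trial_id),
              paste(names(x$config$interval_durations), collapse = "/")))
  invisible(x)
}

#' Replace a dataset's noise
#'
#' Regenerates the noise of an existing dataset at a new amplitude (and
#' optionally model), reusing the trial layout, shapes and mixing.  Handy
#' for setting noise at signal-RMS parity: simulate noise-free, measure
#' [signal_rms()], then add matched noise.
#'
#' @param sim a `scalerp_sim`.
#' @param amplitude new stationary noise RMS (microvolts).
#' @param noise_model,ar_coef override the config's noise settings.
#' @param seed noise seed; defaults to the dataset's seed + 1.
#' @return the dataset with `noise` and `recording` replaced.
#' @export
with_noise <- function(sim, amplitude, noise_model = sim$config$noise_model,
                       ar_coef = sim$config$ar_coef,
                       seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "scalerp_sim"))
  check_scalar_number(amplitude, "amplitude", nonnegative = TRUE)
  n_channels <- nrow(sim$recording$data)
  n_samples <- ncol(sim$recording$data)
  set.seed(seed)
  noise <- matrix(0, n_channels, n_samples)
  if (amplitude > 0) {
    for (ch in seq_len(n_channels)) {
      noise[ch, ] <- if (noise_model == "ar1")
        ar1_noise(n_samples, ar_coef, amplitude)
      else stats::rnorm(n_samples, sd = amplitude)
    }
  }
  sim$noise <- noise
  sim$config$noise_amplitude <- amplitude
  sim$config$noise_model <- noise_model
  data <- Reduce(`+`, sim$truth_contribution) + noise
  sim$recording <- continuous_recording(data, sim$recording$fs,
                                        sim$recording$channel_labels)
  sim
}

#' Noise amplitude giving signal-RMS parity
#'
#' RMS of the summed noiseless signal of a dataset, useful for setting the
#' simulator's noise amplitude so residual RMS matches signal RMS.
#'
#' @param sim a `scalerp_sim`.
#' @return scalar RMS in microvolts.
#' @export
signal_rms <- function(sim) {
  s <- Reduce(`+`, sim$truth_contribution)
  sqrt(mean(s^2))
}
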