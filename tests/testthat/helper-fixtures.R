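# Shared fixtures, all generated in code.

# Small, fast simulation: short intervals, few trials, compact windows.
small_sim_config <- function(seed = 1L, noise_amplitude = 1,
                             noise_model = "white", jitter_sd = 0.05) {
  sim_config(fs = 100,
             interval_durations = c(short = 0.5, medium = 0.8, long = 1.2),
             trials_per_condition = 8,
             inter_trial_gap = c(0.6, 1.0),
             noise_model = noise_model,
             noise_amplitude = noise_amplitude,
             jitter_sd = jitter_sd,
             seed = seed)
}

small_shapes <- function() default_shapes(fs = 100, n_scaled = 40)

small_windows <- list(cue = fixed_window("cue", -200, 800),
                      response = fixed_window("response", -800, 200))

# Design + recording for a small simulated dataset.
small_design <- function(sim, n_scaled = 40) {
  n <- ncol(sim$recording$data)
  blocks <- list(
    build_fixed_block(sim$events, small_windows$cue, n, sim$recording$fs),
    build_fixed_block(sim$events, small_windows$response, n, sim$recording$fs),
    build_scaled_block(sim$events, scaled_spec(n_scaled), n))
  assemble_design(blocks, sim$recording)
}

# Minimal 3-trial event table: cues at given samples, responses D later.
toy_events <- function(cues = c(100, 400, 800), D = c(60, 80, 100),
                       conditions = c("short", "medium", "long"), fs = 100) {
  n <- length(cues)
  D <- rep_len(D, n)
  conditions <- rep_len(conditions, n)
  data.frame(event_id = seq_len(2 * n),
             type = rep(c("cue", "response"), n),
             sample = as.integer(rbind(cues, cues + D)),
             trial_id = rep(seq_len(n), each = 2),
             condition = rep(conditions[seq_len(n)], each = 2),
             response_time_s = rep(D / fs, each = 2),
             stringsAsFactors = FALSE)
}

# Fully connected neighbor graph over n synthetic electrodes.
toy_graph <- function(labels) {
  g <- lapply(labels, function(e) setdiff(labels, e))
  names(g) <- labels
  g
}
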