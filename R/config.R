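## Analysis configuration and run provenance.  A run_config round-trips
## losslessly through JSON, and every CLI command writes its exact config
## snapshot and a timestamped log next to its outputs.

#' Analysis run configuration
#'
#' Bundles every tunable of the rERP pipeline.  Defaults mirror the
#' production-task analysis: 200 Hz sampling, cue window (-200, 800) ms,
#' response window (-800, 200) ms, 330 scaled-time points, the
#' nine-candidate lambda grid with 10-fold cross-validation, a 150 uV
#' continuous-artifact threshold (2000 ms window, 1000 ms step),
#' response-time bounds (0.2, 5) s, and 1000 sign-flip permutations at
#' cluster alpha 0.05.
#'
#' @param fs sampling rate (Hz).
#' @param cue_window,response_window fixed windows `c(pre_ms, post_ms)`.
#' @param n_scaled scaled-time basis points.
#' @param lambda_grid candidate regularization weights.
#' @param cv_folds cross-validation folds.
#' @param artifact_threshold_uv,artifact_window_ms,artifact_step_ms
#'   continuous-artifact parameters.
#' @param rt_bounds_s response-time exclusion bounds in seconds.
#' @param target_channel channel whose CV error selects lambda.
#' @param neighbor_graph path to an adjacency-list file (`NULL` for the
#'   packaged template).
#' @param n_perm,alpha_cell,alpha_cluster permutation-test parameters.
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(fs = 200,
                       cue_window = c(-200, 800),
                       response_window = c(-800, 200),
                       n_scaled = 330,
                       lambda_grid = default_lambda_grid(),
                       cv_folds = 10,
                       artifact_threshold_uv = 150,
                       artifact_window_ms = 2000,
                       artifact_step_ms = 1000,
                       rt_bounds_s = c(0.2, 5),
                       target_channel = 1,
                       neighbor_graph = NULL,
                       n_perm = 1000,
                       alpha_cell = 0.05,
                       alpha_cluster = 0.05,
                       seed = 1L) {
  structure(list(fs = fs, cue_window = cue_window,
                 response_window = response_window, n_scaled = n_scaled,
                 lambda_grid = lambda_grid, cv_folds = cv_folds,
                 artifact_threshold_uv = artifact_threshold_uv,
                 artifact_window_ms = artifact_window_ms,
                 artifact_step_ms = artifact_step_ms,
                 rt_bounds_s = rt_bounds_s,
                 target_channel = target_channel,
                 neighbor_graph = neighbor_graph,
                 n_perm = n_perm, alpha_cell = alpha_cell,
                 alpha_cluster = alpha_cluster, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(vals)) cfg[nm] <- list(vals[[nm]])   # keeps NULLs in place
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## run log: append timestamped messages, flush to text
run_log <- function() {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  env
}

log_msg <- function(log, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  log$lines <- c(log$lines, line)
  invisible(line)
}

write_log <- function(log, path) {
  writeLines(log$lines, path)
  invisible(path)
}

## Build the production-style design from a recording + events + config:
## artifact flagging, RT exclusion, fixed cue/response blocks, scaled block.
build_standard_design <- function(recording, events, config, log = NULL) {
  n <- ncol(recording$data)
  mask <- flag_artifact_samples(recording, config$artifact_threshold_uv,
                                config$artifact_window_ms,
                                config$artifact_step_ms)
  excl <- exclude_response_trials(events, mask,
                                  config$rt_bounds_s[1], config$rt_bounds_s[2])
  events <- excl$events; mask <- excl$mask
  if (!is.null(log))
    log_msg(log, "excluded %.2f%% of samples", 100 * mean(!mask$keep))
  blocks <- list(
    build_fixed_block(events, fixed_window("cue", config$cue_window[1],
                                           config$cue_window[2]), n, recording$fs),
    build_fixed_block(events, fixed_window("response", config$response_window[1],
                                           config$response_window[2]),
                      n, recording$fs),
    build_scaled_block(events, scaled_spec(config$n_scaled), n))
  list(design = assemble_design(blocks, recording, mask), events = events,
       mask = mask)
}
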