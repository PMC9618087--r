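## File formats.  The native interchange is a JSON sidecar (sampling rate,
## channel labels, units) next to a TSV sample matrix, written at full
## precision so round trips are bit-identical.  A thin BrainVision reader
## covers the most common vendor format; EDF and EEGLAB .set require
## dedicated readers that are out of scope here and raise a descriptive
## error.  Events travel as BIDS-style TSV (onset in seconds).

#' Write a recording in the native format
#'
#' Produces `<prefix>.json` (fs, channel labels, units) and
#' `<prefix>_data.tsv` (samples x channels, full-precision text).
#'
#' @param recording a [continuous_recording()].
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "continuous_recording"))
  data_path <- paste0(prefix, "_data.tsv")
  sidecar <- paste0(prefix, ".json")
  m <- t(recording$data)                         # samples x channels
  txt <- apply(m, 2, function(col) formatC(col, format = "g", digits = 17))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(m))
  colnames(txt) <- recording$channel_labels
  utils::write.table(txt, data_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(fs = recording$fs,
                            channel_labels = recording$channel_labels,
                            units = "uV",
                            data_file = basename(data_path)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a continuous recording
#'
#' @param path for `native`: the JSON sidecar written by
#'   [write_recording()]; for `brainvision`: the `.vhdr` header.
#' @param format one of `"native"`, `"brainvision"`, `"edf"`,
#'   `"eeglab_set"`.
#' @param convert_units if `TRUE`, sidecar units of `"V"` are rescaled to
#'   microvolts; otherwise any unit other than microvolts is an error.
#' @return a [continuous_recording()].
#' @export
read_recording <- function(path, format = c("native", "brainvision", "edf",
                                            "eeglab_set"),
                           convert_units = FALSE) {
  format <- match.arg(format)
  switch(format,
         native = read_recording_native(path, convert_units),
         brainvision = read_recording_brainvision(path, convert_units),
         edf = stop_invalid(
           "EDF input requires an external reader; convert to the native format upstream"),
         eeglab_set = stop_invalid(
           "EEGLAB .set input requires an external reader; convert to the native format upstream"))
}

read_recording_native <- function(path, convert_units) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$fs) || is.null(meta$data_file))
    stop_invalid("corrupt sidecar: %s", path)
  scale <- 1
  units <- meta$units %||% "uV"
  if (!units %in% c("uV", "µV", "microvolts")) {
    if (units == "V" && convert_units) scale <- 1e6
    else stop_invalid("sidecar units are '%s'; pass convert_units = TRUE for volts",
                      units)
  }
  data_path <- file.path(dirname(path), meta$data_file)
  m <- as.matrix(utils::read.delim(data_path, check.names = FALSE))
  continuous_recording(t(m) * scale, meta$fs, meta$channel_labels)
}

## minimal BrainVision reader: INI-style .vhdr + binary multiplexed data
read_recording_brainvision <- function(path, convert_units) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  getval <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0) stop_invalid("corrupt header: missing %s", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  if (toupper(getval("DataFormat")) != "BINARY")
    stop_invalid("only BINARY BrainVision data is supported")
  if (toupper(getval("DataOrientation")) != "MULTIPLEXED")
    stop_invalid("only MULTIPLEXED BrainVision data is supported")
  n_ch <- as.integer(getval("NumberOfChannels"))
  fs <- 1e6 / as.numeric(getval("SamplingInterval"))
  fmt <- toupper(getval("BinaryFormat"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != n_ch) stop_invalid("channel list does not match NumberOfChannels")
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[[`, "", 1)
  resolution <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  data_path <- file.path(dirname(path), getval("DataFile"))
  size <- file.info(data_path)$size
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(data_path, "numeric", n = size / 4, size = 4),
    INT_16 = readBin(data_path, "integer", n = size / 2, size = 2, signed = TRUE),
    stop_invalid("unsupported BinaryFormat: %s", fmt))
  n_samp <- length(raw) %/% n_ch
  m <- matrix(raw[seq_len(n_samp * n_ch)], nrow = n_ch)   # multiplexed
  m <- m * resolution
  continuous_recording(m, fs, labels)
}

#' Write a BIDS-style events TSV
#'
#' Columns `onset` (seconds), `duration`, `trial_type`, `trial_id`,
#' `response_time`.
#'
#' @param events internal event table (0-based `sample` column).
#' @param path output TSV.
#' @param fs sampling rate used to convert samples to seconds.
#' @export
write_events <- function(events, path, fs) {
  df <- data.frame(onset = events$sample / fs,
                   duration = 0,
                   trial_type = events$type,
                   trial_id = events$trial_id,
                   response_time = events$response_time_s)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Onsets in seconds are converted to 0-based samples by round-half-up at
#' `fs`.  Cue/response pairing is validated: every `trial_id` carrying
#' interval events must have exactly one of each delimiting type.
#'
#' @param path TSV with columns `onset`, `trial_type` and optionally
#'   `trial_id`, `response_time`.
#' @param fs sampling rate (Hz).
#' @param start_event,end_event interval-delimiting event types to
#'   validate (set to `NULL` to skip validation).
#' @return internal event table `data.frame`.
#' @export
read_events <- function(path, fs, start_event = "cue", end_event = "response") {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "trial_type") %in% names(df)))
    stop_invalid("events file needs columns onset and trial_type")
  ev <- data.frame(event_id = seq_len(nrow(df)),
                   type = df$trial_type,
                   sample = as.integer(round_half_up(df$onset * fs)),
                   trial_id = df$trial_id %||% seq_len(nrow(df)),
                   condition = df$condition %||% NA_character_,
                   response_time_s = df$response_time %||% NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(start_event)) {
    iv <- ev[ev$type %in% c(start_event, end_event), , drop = FALSE]
    counts <- table(iv$trial_id, iv$type)
    bad <- rownames(counts)[apply(counts != 1, 1, any)]
    if (length(bad) > 0)
      stop_invalid("unpaired %s/%s events for trial_id(s): %s",
                   start_event, end_event, paste(bad, collapse = ", "))
  }
  ev
}

#' Export estimated waveforms as TSV
#'
#' One file per component: an axis column (`lag_ms` or
#' `elapsed_fraction`) plus one column per channel.
#'
#' @param fit a `rerp_fit`.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_waveforms <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (comp in unique(fit$columns$component)) {
    w <- get_waveform(fit, comp)
    axis_name <- if (comp == "scaled") "elapsed_fraction" else "lag_ms"
    df <- data.frame(attr(w, "axis"), t(w))
    names(df) <- c(axis_name, fit$channel_labels)
    p <- file.path(dir, paste0("waveform_", comp, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
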