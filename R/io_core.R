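# Core domain types: recordings, event lists, epochs; CSV readers/writers.

.DEFAULT_CHANNELS <- c("F7", "Fp1", "Fp2", "F8")
.DEVICES <- c("garment", "dry")
.TASKS <- c("ec_rest", "eo_rest", "movement", "artifact")

#' Four-channel forehead EEG recording
#'
#' Container for a multichannel EEG time series in microvolts, channels in
#' rows. The pipeline assumes the sub-hairline montage F7, Fp1, Fp2, F8
#' sampled at 256 Hz, but any channel set/rate can be stored.
#'
#' @param data Numeric matrix, channels x samples, in uV.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Character vector, one label per row of `data`.
#' @param subject_id Subject identifier (string).
#' @param device `"garment"`, `"dry"` or `NA`.
#' @param task One of `"ec_rest"`, `"eo_rest"`, `"movement"`, `"artifact"`
#'   or `NA`.
#' @return An object of class `"eeg_recording"`.
#' @export
new_recording <- function(data, fs, channel_names = .DEFAULT_CHANNELS,
                          subject_id = NA_character_, device = NA_character_,
                          task = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  if (anyNA(data)) stop("recording contains missing values")
  if (length(channel_names) != nrow(data)) {
    stop("schema error: ", length(channel_names), " channel names for ",
         nrow(data), " data rows")
  }
  if (!is.na(device) && !device %in% .DEVICES) {
    stop("unknown device '", device, "'")
  }
  if (!is.na(task) && !task %in% .TASKS) stop("unknown task '", task, "'")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, device = device, task = task),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " ch x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 2), " s)\n",
      sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "),
      " | subject: ", x$subject_id, " | device: ", x$device,
      " | task: ", x$task, "\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

# Canonicalize channel label aliases ("FP1" -> "Fp1", "fp2" -> "Fp2", ...).
normalize_channel_names <- function(labels) {
  up <- toupper(trimws(labels))
  canon <- c(F7 = "F7", FP1 = "Fp1", FP2 = "Fp2", F8 = "F8")
  out <- labels
  hit <- up %in% names(canon)
  out[hit] <- canon[up[hit]]
  out
}

#' Event list for a recording
#'
#' Events are stored as 0-based sample indices (exact at 256 Hz, no
#' rounding ambiguity), a label, and a duration in samples.
#'
#' @param onset_sample Integer vector of 0-based onsets, strictly increasing.
#' @param label Character vector of event labels.
#' @param duration_samples Integer vector of durations (> 0).
#' @return A `data.frame` of class `"event_list"`.
#' @export
event_list <- function(onset_sample, label, duration_samples) {
  onset_sample <- as.integer(round(onset_sample))
  duration_samples <- as.integer(round(duration_samples))
  n <- length(onset_sample)
  if (length(label) != n || length(duration_samples) != n) {
    stop("event fields must have equal length")
  }
  if (n > 0) {
    if (any(onset_sample < 0)) stop("event onsets must be >= 0")
    if (any(duration_samples <= 0)) stop("event durations must be > 0")
    if (is.unsorted(onset_sample, strictly = TRUE)) {
      stop("event onsets must be strictly increasing")
    }
  }
  structure(data.frame(onset_sample = onset_sample,
                       label = as.character(label),
                       duration_samples = duration_samples,
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Read a recording from CSV
#'
#' Expects a header row with an optional time column (`time_s`, `time` or
#' `t`, in seconds) plus one column per channel, body numeric, in uV.
#' Rows are samples. The sampling rate is taken from `fs` or, if absent,
#' inferred as the reciprocal of the median time step.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; `NULL` to infer from a time column.
#' @param channels Channel labels that must be present (alias-tolerant,
#'   e.g. "FP1" matches "Fp1"). Use `NULL` to accept whatever is present.
#' @param subject_id,device,task Metadata stored on the recording.
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path, fs = NULL, channels = .DEFAULT_CHANNELS,
                               subject_id = NA_character_,
                               device = NA_character_, task = NA_character_) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("empty recording file: ", path)
  names(raw) <- normalize_channel_names(names(raw))
  time_col <- intersect(c("time_s", "time", "t"), names(raw))[1]

  num <- vector("list", ncol(raw))
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]) & nzchar(raw[[j]]))
    if (anyNA(v)) {
      line <- if (length(bad)) bad[1] + 1L else which(is.na(v))[1] + 1L
      stop("parse error: non-numeric value in column '", names(raw)[j],
           "' at line ", line, " of ", path)
    }
    num[[j]] <- v
  }
  names(num) <- names(raw)

  if (is.null(fs)) {
    if (is.na(time_col)) {
      stop("no 'fs' given and no time column found in ", path)
    }
    dt <- stats::median(diff(num[[time_col]]))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer fs from time column")
    fs <- 1 / dt
  }
  ch_cols <- setdiff(names(num), c("time_s", "time", "t"))
  if (!is.null(channels)) {
    channels <- normalize_channel_names(channels)
    missing_ch <- setdiff(channels, ch_cols)
    if (length(missing_ch)) {
      stop("schema error: missing channel column(s): ",
           paste(missing_ch, collapse = ", "))
    }
    ch_cols <- channels
  }
  data <- t(do.call(cbind, num[ch_cols]))  # channels x samples
  new_recording(data, fs = fs, channel_names = ch_cols,
                subject_id = subject_id, device = device, task = task)
}

#' Write a recording to CSV (samples in rows, uV)
#' @param rec An `eeg_recording`.
#' @param path Output path.
#' @param include_time Prepend a `time_s` column.
#' @export
write_recording_csv <- function(rec, path, include_time = TRUE) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_names
  if (include_time) {
    df <- cbind(time_s = (seq_len(ncol(rec$data)) - 1L) / rec$fs, df)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an events CSV (`onset_sample,label,duration_samples`)
#' @param path CSV path.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "label", "duration_samples")
  if (!all(need %in% names(df))) {
    stop("events file must have columns ", paste(need, collapse = ", "))
  }
  event_list(df$onset_sample, df$label, df$duration_samples)
}

#' Write an events CSV
#' @param events An `event_list`.
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Cut epochs around labelled events
#'
#' Extracts one epoch per event carrying `label`, with a time axis in
#' seconds whose zero lies at the event onset. Epochs whose window would
#' cross a recording boundary are dropped (their count is reported in the
#' result and via a message).
#'
#' @param rec An `eeg_recording`.
#' @param events An `event_list`.
#' @param label Event label to epoch on.
#' @param tmin_s,tmax_s Window relative to onset, seconds (`tmin_s < tmax_s`).
#' @return An object of class `"epoch_set"`: `data` (trials x channels x
#'   samples), `fs`, `time_axis`, `event_label`, `channel_names`,
#'   `n_dropped`.
#' @export
extract_epochs <- function(rec, events, label, tmin_s, tmax_s) {
  if (!is.numeric(tmin_s) || !is.numeric(tmax_s) || tmin_s >= tmax_s) {
    stop("argument error: need tmin_s < tmax_s")
  }
  onsets <- events$onset_sample[events$label == label]
  if (length(onsets) == 0L) stop("no events with label '", label, "'")
  onsets <- sort(onsets)
  fs <- rec$fs
  i0 <- as.integer(round(tmin_s * fs))
  i1 <- as.integer(round(tmax_s * fs))
  time_axis <- (i0:i1) / fs
  n <- ncol(rec$data)
  lo <- onsets + i0          # 0-based first sample of each epoch
  hi <- onsets + i1
  ok <- lo >= 0L & hi <= n - 1L
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " epoch(s) dropped: window exceeds recording bounds")
  }
  onsets <- onsets[ok]
  if (length(onsets) == 0L) stop("all epochs fall outside the recording")
  n_ch <- nrow(rec$data)
  len <- length(time_axis)
  arr <- array(NA_real_, dim = c(length(onsets), n_ch, len))
  for (k in seq_along(onsets)) {
    arr[k, , ] <- rec$data[, (onsets[k] + i0 + 1L):(onsets[k] + i1 + 1L)]
  }
  structure(list(data = arr, fs = fs, time_axis = time_axis,
                 event_label = label, channel_names = rec$channel_names,
                 n_dropped = n_dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " ch x ", dim(x$data)[3], " samples @ ", x$fs, " Hz, t in [",
      round(min(x$time_axis), 3), ", ", round(max(x$time_axis), 3),
      "] s, label '", x$event_label, "'\n", sep = "")
  invisible(x)
}
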