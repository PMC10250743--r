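# Power spectral density estimation and band-power comparisons.

#' Welch power spectral density of a recording
#'
#' Hamming-windowed segments of `psd_window_s` seconds, hop = window minus
#' overlap (the 30 ms default overlap is rounded to whole samples), each
#' zero-padded to `psd_nfft` points. Segment periodograms are averaged in
#' linear power and log10 is applied last; the grid is truncated to the
#' 0-60 Hz analysis range. Power is floored at 1e-20 uV^2/Hz before the
#' log so all-zero input stays finite.
#'
#' The recording is expected to be band-pass filtered (0.1-100 Hz in the
#' standard pipeline) beforehand.
#'
#' @param rec An `eeg_recording`.
#' @param cfg An [analysis_config()].
#' @param fmax_hz Upper edge of the retained grid (default 60).
#' @return An object of class `"eeg_spectrum"`: `freqs` (Hz), `log_power`
#'   (channels x freqs, log10 of uV^2/Hz), `fs`, `nfft` and recording
#'   metadata (`subject_id`, `device`, `task`, `action`).
#' @export
compute_psd <- function(rec, cfg = analysis_config(), fmax_hz = 60) {
  fs <- rec$fs
  wl <- round(cfg$psd_window_s * fs)
  n <- ncol(rec$data)
  if (n < wl) stop("length error: recording shorter than one PSD window")
  nfft <- cfg$psd_nfft
  if (nfft < wl) stop("psd_nfft must be >= the window length")
  hop <- wl - round(cfg$psd_overlap_s * fs)
  if (hop < 1) stop("overlap leaves no hop")
  starts <- seq(1L, n - wl + 1L, by = hop)
  win <- signal::hamming(wl)
  U <- sum(win^2)

  n_keep <- nfft %/% 2 + 1L
  freqs <- (seq_len(n_keep) - 1) * fs / nfft
  acc <- matrix(0, nrow(rec$data), n_keep)
  seg <- matrix(0, nfft, length(starts))
  for (ch in seq_len(nrow(rec$data))) {
    for (j in seq_along(starts)) {
      seg[seq_len(wl), j] <- rec$data[ch, starts[j]:(starts[j] + wl - 1L)] * win
    }
    X <- stats::mvfft(seg)[seq_len(n_keep), , drop = FALSE]
    P <- (Mod(X)^2) / (fs * U)
    P[2:(n_keep - 1L), ] <- 2 * P[2:(n_keep - 1L), ]   # one-sided
    acc[ch, ] <- rowMeans(P)
  }
  keep <- freqs <= fmax_hz
  log_power <- log10(pmax(acc[, keep, drop = FALSE], 1e-20))
  rownames(log_power) <- rec$channel_names
  structure(list(freqs = freqs[keep], log_power = log_power,
                 fs = fs, nfft = nfft, n_segments = length(starts),
                 subject_id = rec$subject_id, device = rec$device,
                 task = rec$task,
                 action = if (!is.null(rec$action)) rec$action else NA_character_),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat("<eeg_spectrum> ", nrow(x$log_power), " ch x ", length(x$freqs),
      " bins (", min(x$freqs), "-", max(x$freqs), " Hz, d = ",
      signif(diff(x$freqs[1:2]), 3), " Hz), ", x$n_segments,
      " Welch segments\n", sep = "")
  invisible(x)
}

#' Band-power table across spectra
#'
#' For each spectrum: log power is averaged over the four electrodes per
#' bin (the "average electrode"), then averaged over the bins whose center
#' lies inside each band (inclusive edges: `lo <= center <= hi`; at 0.25 Hz
#' spacing adjacent bands such as 0-3 and 4-7 Hz share no bins).
#'
#' @param spectra A list of `eeg_spectrum` objects carrying subject/device/
#'   task (and optionally action) metadata.
#' @param cfg An [analysis_config()] (defines the bands).
#' @return A `data.frame` with key columns `subject`, `device`, `task`,
#'   `action` and one column of mean log10 power per band.
#' @export
band_power_table <- function(spectra, cfg = analysis_config()) {
  if (length(spectra) == 0L) stop("no spectra given")
  f0 <- spectra[[1]]$freqs
  rows <- lapply(spectra, function(sp) {
    if (length(sp$freqs) != length(f0) || any(abs(sp$freqs - f0) > 1e-9)) {
      stop("alignment error: spectra on different frequency grids")
    }
    avg <- colMeans(sp$log_power)
    vals <- vapply(cfg$bands, function(b) {
      mean(avg[f0 >= b[1] & f0 <= b[2]])
    }, 0)
    c(list(subject = sp$subject_id, device = sp$device, task = sp$task,
           action = sp$action), as.list(vals))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Split an artifact-induction recording into per-action segments
#'
#' @param rec An `eeg_recording`.
#' @param events An [event_list()] whose entries partition the recording
#'   into labelled, non-overlapping segments.
#' @return A list (named by action label) of `eeg_recording` objects, each
#'   with an `action` field set.
#' @export
segment_by_action <- function(rec, events) {
  if (nrow(events) == 0L) return(list())
  ends <- events$onset_sample + events$duration_samples
  if (any(ends > ncol(rec$data))) {
    stop("schedule error: segment runs past the end of the recording")
  }
  if (any(events$onset_sample[-1] < ends[-length(ends)])) {
    stop("schedule error: overlapping segments")
  }
  out <- lapply(seq_len(nrow(events)), function(k) {
    cols <- (events$onset_sample[k] + 1L):ends[k]
    sub <- new_recording(rec$data[, cols, drop = FALSE], fs = rec$fs,
                         channel_names = rec$channel_names,
                         subject_id = rec$subject_id, device = rec$device,
                         task = rec$task)
    sub$action <- events$label[k]
    sub
  })
  names(out) <- events$label
  out
}

#' Paired device comparison of band power
#'
#' Pairs the garment and dry rows of a band-power table by subject for one
#' task (and optionally one action) and runs the two-sided paired Wilcoxon
#' signed-rank test on the band means. Direction is the sign of the median
#' paired difference (garment minus dry).
#'
#' @param table Output of [band_power_table()].
#' @param band Band column name (e.g. `"alpha"`).
#' @param task Task to compare.
#' @param action Optional action label (per-action comparisons).
#' @return A list: `W`, `p`, `direction` (-1/0/1), `n` subjects.
#' @export
compare_devices_by_band <- function(table, band, task, action = NULL) {
  if (!band %in% names(table)) stop("unknown band '", band, "'")
  rows <- table[table$task == task, , drop = FALSE]
  if (!is.null(action)) rows <- rows[!is.na(rows$action) & rows$action == action, ]
  g <- rows[rows$device == "garment", ]
  d <- rows[rows$device == "dry", ]
  subjects <- sort(unique(rows$subject))
  if (!all(subjects %in% g$subject) || !all(subjects %in% d$subject)) {
    stop("pairing error: every subject needs both devices for task '",
         task, "'")
  }
  x <- g[[band]][match(subjects, g$subject)]
  y <- d[[band]][match(subjects, d$subject)]
  res <- wilcoxon_signed_rank(x, y, alternative = "two.sided")
  list(W = res$W, p = res$p.value,
       direction = sign(stats::median(x - y)), n = length(subjects))
}
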