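# Filtering, amplitude-outlier removal and trial rejection.

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
# The pad length follows the impulse-response heuristic 3 * fs / f_edge
# (three time constants of the slowest edge), capped at n - 1.
.filtfilt_refl <- function(flt, x, padlen) {
  n <- length(x)
  padlen <- max(1L, min(n - 1L, as.integer(padlen)))
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  y <- signal::filter(flt, ext)
  y <- rev(signal::filter(flt, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

# Apply a single-sided (low/high) Butterworth zero-phase per matrix row.
.apply_butter <- function(data, fs, cutoff_hz, type, order) {
  w <- cutoff_hz / (fs / 2)
  flt <- signal::butter(order, w, type = type)
  padlen <- round(3 * fs / cutoff_hz)
  min_n <- 3 * (2 * order + 1)
  if (ncol(data) <= min_n) {
    stop("padding error: recording too short for filter warm-up (",
         ncol(data), " samples)")
  }
  t(apply(data, 1, function(x) .filtfilt_refl(flt, x, padlen)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order (by default) Butterworth design forward and backward
#' per channel, so the output is zero-phase and the effective magnitude
#' response is the squared design response. The band-pass is realized as a
#' high-pass/low-pass cascade of single-sided designs, which stays
#' numerically robust down to the 0.1 Hz broadband edge. `lo_hz = 0` gives
#' a pure low-pass, `hi_hz = Inf` a pure high-pass.
#'
#' @param rec An `eeg_recording`.
#' @param lo_hz,hi_hz Band edges in Hz, `0 <= lo_hz < hi_hz`; `hi_hz` must
#'   be below the Nyquist frequency (or `Inf`).
#' @param order Design order of each directional pass (default 4).
#' @return The filtered `eeg_recording` (same length).
#' @export
bandpass <- function(rec, lo_hz, hi_hz, order = 4L) {
  fs <- rec$fs
  if (lo_hz < 0 || hi_hz <= lo_hz) stop("argument error: need 0 <= lo_hz < hi_hz")
  if (is.finite(hi_hz) && hi_hz >= fs / 2) {
    stop("argument error: hi_hz must be below the Nyquist frequency ", fs / 2)
  }
  if (lo_hz == 0 && !is.finite(hi_hz)) return(rec)
  data <- rec$data
  if (is.finite(hi_hz)) {
    data <- .apply_butter(data, fs, hi_hz, "low", order)
  }
  if (lo_hz > 0) {
    data <- .apply_butter(data, fs, lo_hz, "high", order)
  }
  out <- rec
  out$data <- data
  rownames(out$data) <- rec$channel_names
  out
}

# Analytic-signal envelope via the frequency-domain Hilbert transform.
.hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Hilbert-envelope amplitude-outlier removal
#'
#' Per channel: high-pass at `hp_hz` (4th-order zero-phase Butterworth),
#' take the magnitude of the analytic signal, z-score it (per channel), and
#' flag samples whose z exceeds `z_thresh` above the mean (one-sided, as
#' only large envelopes indicate artifacts). Flagged samples are replaced
#' in the ORIGINAL signal by linear interpolation between the nearest
#' unflagged neighbours; flags touching the recording edges are filled by
#' nearest-value extension. This step is intended for resting-state
#' recordings; artifact-induction recordings are analyzed unclean on
#' purpose.
#'
#' @param rec An `eeg_recording`.
#' @param hp_hz High-pass edge of the detector (default 60 Hz; requires
#'   `fs > 2 * hp_hz`).
#' @param z_thresh Envelope z-score threshold (default 5).
#' @param env_floor_uv Absolute envelope floor in uV (default 0.01). A
#'   sample is only flagged if its envelope also exceeds
#'   `max(env_floor_uv, 1%% of the channel RMS)`: the z-score is
#'   scale-free, so without a floor a channel with essentially no
#'   high-frequency content (e.g. a noiseless synthetic sinusoid) would
#'   flag its own filtering residue. Both floors sit far below the
#'   high-frequency noise level of any physical EEG recording.
#' @return A list with `recording` (cleaned) and `mask` (class
#'   `"outlier_mask"`: logical channels x samples matrix, per-channel
#'   counts and overall flagged fraction).
#' @export
remove_amplitude_outliers <- function(rec, hp_hz = 60, z_thresh = 5,
                                      env_floor_uv = 0.01) {
  fs <- rec$fs
  if (fs <= 2 * hp_hz) stop("argument error: need fs > 2 * hp_hz")
  n <- ncol(rec$data)
  filtered <- .apply_butter(rec$data, fs, hp_hz, "high", order = 4L)
  mask <- matrix(FALSE, nrow = nrow(rec$data), ncol = n)
  cleaned <- rec$data
  for (ch in seq_len(nrow(rec$data))) {
    env <- .hilbert_envelope(filtered[ch, ])
    floor_ch <- max(env_floor_uv, 0.01 * sqrt(mean(rec$data[ch, ]^2)))
    if (stats::sd(env) == 0) {
      flag <- rep(FALSE, n)                 # constant envelope, nothing to flag
    } else {
      z <- (env - mean(env)) / stats::sd(env)
      flag <- z > z_thresh & env > floor_ch
    }
    if (all(flag)) {
      stop("degenerate channel: all samples flagged on ",
           rec$channel_names[ch])
    }
    mask[ch, ] <- flag
    if (any(flag)) {
      keep <- which(!flag)
      cleaned[ch, flag] <- stats::approx(keep, rec$data[ch, keep],
                                         xout = which(flag), rule = 2)$y
    }
  }
  out <- rec
  out$data <- cleaned
  rownames(out$data) <- rec$channel_names
  m <- structure(list(mask = mask,
                      n_flagged = rowSums(mask),
                      fraction = mean(mask),
                      channel_names = rec$channel_names),
                 class = "outlier_mask")
  list(recording = out, mask = m)
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat("<outlier_mask> flagged fraction ", signif(x$fraction, 3), "; per channel: ",
      paste(x$channel_names, x$n_flagged, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Reject high-amplitude trials
#'
#' A trial is removed iff the maximum absolute amplitude over all channels
#' and samples strictly exceeds `v_max_uv` (a trial reaching exactly the
#' ceiling is kept). Survivor order is preserved.
#'
#' @param epochs An `epoch_set`.
#' @param v_max_uv Amplitude ceiling in uV (default 250).
#' @return A list with `epochs` (survivors), `kept_indices` (1-based
#'   indices into the input trials) and `n_rejected`.
#' @export
reject_trials <- function(epochs, v_max_uv = 250) {
  n_tr <- dim(epochs$data)[1]
  if (n_tr == 0L) stop("empty epoch set")
  amax <- apply(abs(epochs$data), 1, max)
  keep <- amax <= v_max_uv
  if (!any(keep)) {
    stop("all ", n_tr, " trials rejected at ", v_max_uv, " uV")
  }
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  list(epochs = out, kept_indices = which(keep),
       n_rejected = sum(!keep))
}
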