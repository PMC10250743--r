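# Morlet-wavelet time-frequency decomposition and ERD/ERS maps.

#' Morlet-wavelet time-frequency representation of epochs
#'
#' Convolves every trial and channel with complex Morlet wavelets (constant
#' `n_cycles`, default 7, i.e. Gaussian envelope SD `n_cycles / (2 pi f)` in
#' time) on the frequency grid `seq(fmin, fmax, by = df)` and stores the
#' squared magnitude. Wavelets are L2-normalized; the absolute power scale
#' is arbitrary (ERD/ERS maps are ratios, so it cancels). Samples within
#' one wavelet half-length of either epoch edge are flagged in `edges`; they
#' are retained, not excluded.
#'
#' Epochs are expected to come from a recording already band-pass filtered
#' to the movement band (0.3-30 Hz in the standard pipeline).
#'
#' @param epochs An `epoch_set`.
#' @param fmin,fmax,df Frequency grid in Hz (defaults 5-30 at 0.25).
#' @param n_cycles Wavelet cycles (constant across frequencies).
#' @param decim Keep every `decim`-th time sample (power varies slowly;
#'   decimation keeps large sessions in memory).
#' @return An object of class `"eeg_tfr"`: `power` (trials x channels x
#'   freqs x times, uV^2 up to the wavelet scale), `freqs`, `times`, `fs`,
#'   `channel_names`, `edges` (freqs x times logical).
#' @export
morlet_tfr <- function(epochs, fmin = 5, fmax = 30, df = 0.25,
                       n_cycles = 7, decim = 1L) {
  fs <- epochs$fs
  freqs <- seq(fmin, fmax, by = df)
  L <- length(epochs$time_axis)
  n_tr <- dim(epochs$data)[1]
  n_ch <- dim(epochs$data)[2]

  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- ceiling(5 * sigma_t * fs)              # 5 SD support half-length
  if (2 * max(half) + 1 > L) {
    stop("length error: epoch shorter than the wavelet support at ",
         fmin, " Hz")
  }
  wav_len <- 2L * max(half) + 1L
  nfft <- stats::nextn(L + wav_len - 1L, 2)

  # precompute wavelet FFTs (wavelet centered at sample max(half) + 1)
  wf <- matrix(0i, nfft, length(freqs))
  for (j in seq_along(freqs)) {
    tt <- (-half[j]:half[j]) / fs
    w <- exp(2i * pi * freqs[j] * tt) * exp(-tt^2 / (2 * sigma_t[j]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    buf <- complex(length.out = nfft)
    buf[(max(half) - half[j] + 1L):(max(half) + half[j] + 1L)] <- w
    wf[, j] <- stats::fft(buf)
  }

  t_idx <- seq(1L, L, by = as.integer(decim))
  times <- epochs$time_axis[t_idx]
  shift <- max(half)                              # convolution group delay
  power <- array(0, dim = c(n_tr, n_ch, length(freqs), length(t_idx)))
  pad <- complex(length.out = nfft)
  for (tr in seq_len(n_tr)) {
    for (ch in seq_len(n_ch)) {
      x <- pad
      x[seq_len(L)] <- epochs$data[tr, ch, ]
      X <- stats::fft(x)
      for (j in seq_along(freqs)) {
        conv <- stats::fft(X * wf[, j], inverse = TRUE) / nfft
        power[tr, ch, j, ] <- Mod(conv[shift + t_idx])^2
      }
    }
  }
  edges <- matrix(FALSE, length(freqs), length(t_idx))
  for (j in seq_along(freqs)) {
    edges[j, ] <- t_idx <= half[j] | t_idx > L - half[j]
  }
  structure(list(power = power, freqs = freqs, times = times, fs = fs,
                 channel_names = epochs$channel_names, edges = edges,
                 n_cycles = n_cycles),
            class = "eeg_tfr")
}

#' ERD/ERS maps from a time-frequency representation
#'
#' Power is first averaged over trials; per frequency, the reference power
#' is the mean over the baseline interval; the map is the percent change
#' `100 * (P(f, t) - P_ref(f)) / P_ref(f)`. By construction values never
#' drop below -100 and the map averages to 0 over the baseline itself.
#'
#' @param tfr An `eeg_tfr`.
#' @param baseline_s `c(lo, hi)` baseline interval in seconds relative to
#'   the cue (default `c(-5, -2)`, inside the preceding rest period).
#' @return A list of per-channel objects of class `"erds_map"`: `map`
#'   (freqs x times, percent), `freqs`, `times`, `baseline_s`, `channel`.
#' @export
erds <- function(tfr, baseline_s = c(-5, -2)) {
  if (length(baseline_s) != 2 || baseline_s[1] >= baseline_s[2]) {
    stop("argument error: baseline_s must be c(lo, hi) with lo < hi")
  }
  bl <- tfr$times >= baseline_s[1] & tfr$times <= baseline_s[2]
  if (!any(bl)) stop("argument error: baseline interval outside the epoch")
  avg <- apply(tfr$power, c(2, 3, 4), mean)      # channels x freqs x times
  lapply(seq_along(tfr$channel_names), function(ch) {
    P <- matrix(avg[ch, , ], length(tfr$freqs), length(tfr$times))
    P_ref <- rowMeans(P[, bl, drop = FALSE])
    if (any(P_ref <= 0)) {
      stop("degenerate baseline: zero reference power at some frequency")
    }
    structure(list(map = 100 * (P / P_ref - 1), freqs = tfr$freqs,
                   times = tfr$times, baseline_s = baseline_s,
                   channel = tfr$channel_names[ch]),
              class = "erds_map")
  })
}

#' @export
print.erds_map <- function(x, ...) {
  cat("<erds_map> channel ", x$channel, ": ", length(x$freqs), " freqs x ",
      length(x$times), " times, range [", round(min(x$map), 1), ", ",
      round(max(x$map), 1), "] %\n", sep = "")
  invisible(x)
}

.check_same_grid <- function(maps) {
  f0 <- maps[[1]]$freqs; t0 <- maps[[1]]$times
  for (m in maps) {
    if (length(m$freqs) != length(f0) || any(abs(m$freqs - f0) > 1e-9) ||
        length(m$times) != length(t0) || any(abs(m$times - t0) > 1e-9)) {
      stop("alignment error: ERD/ERS maps on different grids")
    }
  }
}

#' Grand-average ERD/ERS map
#'
#' Arithmetic mean of maps sharing one grid; used first across electrodes
#' (after trial averaging inside [erds()]) and then across subjects,
#' matching the study's averaging order.
#'
#' @param maps A list of `erds_map` objects.
#' @param channel Label for the averaged map.
#' @return An `erds_map`.
#' @export
grand_average_erds <- function(maps, channel = "average") {
  if (length(maps) == 0L) stop("no maps to average")
  .check_same_grid(maps)
  acc <- Reduce(`+`, lapply(maps, `[[`, "map")) / length(maps)
  structure(list(map = acc, freqs = maps[[1]]$freqs,
                 times = maps[[1]]$times,
                 baseline_s = maps[[1]]$baseline_s, channel = channel),
            class = "erds_map")
}

#' Bin-wise paired device comparison of ERD/ERS maps
#'
#' For each time-frequency bin, runs a two-sided paired Wilcoxon
#' signed-rank test across subjects (one electrode-averaged map per subject
#' and device; no multiple-comparison correction). The significance mask
#' (`p < alpha`) is applied to the dry-minus-garment difference map:
#' non-significant bins are zeroed.
#'
#' @param maps_garment,maps_dry Lists of per-subject `erds_map` objects in
#'   the same subject order.
#' @param alpha Bin-wise significance level (default 0.05).
#' @return A list: `p` (freqs x times), `mask` (logical), `diff`
#'   (dry - garment, percent), `masked_diff`, `freqs`, `times`, `alpha`,
#'   `n_subjects`.
#' @export
binwise_device_comparison <- function(maps_garment, maps_dry, alpha = 0.05) {
  n <- length(maps_garment)
  if (length(maps_dry) != n) {
    stop("pairing error: ", n, " garment maps vs ", length(maps_dry), " dry")
  }
  if (n < 2) stop("need at least 2 subjects")
  .check_same_grid(c(maps_garment, maps_dry))
  nf <- length(maps_garment[[1]]$freqs)
  nt <- length(maps_garment[[1]]$times)
  G <- vapply(maps_garment, `[[`, matrix(0, nf, nt), "map")  # nf x nt x n
  D <- vapply(maps_dry, `[[`, matrix(0, nf, nt), "map")
  p <- matrix(NA_real_, nf, nt)
  for (i in seq_len(nf)) {
    for (j in seq_len(nt)) {
      p[i, j] <- wilcoxon_signed_rank(D[i, j, ], G[i, j, ])$p.value
    }
  }
  diff_map <- apply(D - G, c(1, 2), mean)
  mask <- p < alpha
  list(p = p, mask = mask, diff = diff_map,
       masked_diff = diff_map * mask,
       freqs = maps_garment[[1]]$freqs, times = maps_garment[[1]]$times,
       alpha = alpha, n_subjects = n)
}
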