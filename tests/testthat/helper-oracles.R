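# Shared test helpers: independent oracles and tiny fixtures.

# Brute-force exact signed-rank p-value by enumerating all 2^m sign
# assignments of the observed (midrank) ranks. Independent of the
# convolution implementation; only feasible for small m.
brute_force_wsr_p <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- vapply(0:(2^m - 1), function(bits) {
    sum(r[bitwAnd(bits, 2^(seq_len(m) - 1)) > 0])
  }, 0)
  p_ge <- mean(Ws >= W_obs - 1e-12)
  p_le <- mean(Ws <= W_obs + 1e-12)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Minimal epoch_set around a single sinusoid (or custom matrix).
toy_epochs <- function(data_array, fs = 256, tmin = NULL) {
  L <- dim(data_array)[3]
  if (is.null(tmin)) tmin <- -(L - 1) / (2 * fs)
  i0 <- round(tmin * fs)
  structure(list(data = data_array, fs = fs,
                 time_axis = (i0:(i0 + L - 1)) / fs,
                 event_label = "movement",
                 channel_names = paste0("ch", seq_len(dim(data_array)[2])),
                 n_dropped = 0L),
            class = "epoch_set")
}

# Hand-built eeg_spectrum on a shared toy grid.
toy_spectrum <- function(log_power, freqs, subject = "S01",
                         device = "garment", task = "ec_rest",
                         action = NA_character_) {
  structure(list(freqs = freqs, log_power = log_power, fs = 256,
                 nfft = 1024, n_segments = 1, subject_id = subject,
                 device = device, task = task, action = action),
            class = "eeg_spectrum")
}

# Hand-built erds_map on a shared grid.
toy_map <- function(map, freqs = seq_len(nrow(map)),
                    times = seq_len(ncol(map)), channel = "average") {
  structure(list(map = map, freqs = freqs, times = times,
                 baseline_s = c(-5, -2), channel = channel),
            class = "erds_map")
}

# Mean log10 band power of the electrode average of a spectrum.
band_mean <- function(sp, lo, hi) {
  mean(colMeans(sp$log_power)[sp$freqs >= lo & sp$freqs <= hi])
}
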