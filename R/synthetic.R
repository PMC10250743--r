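# Seeded synthetic EEG sessions with the statistical structure the
# analysis assumes: 1/f background with shared frontal sources, alpha
# reactivity, movement-locked desynchronization, scripted artifacts, and
# device-dependent mains pickup.

.SYNTH_FS <- 256
.PINK_RHO <- 0.7   # inter-channel correlation of the 1/f background

#' Synthetic subject profile
#'
#' Spectral "personality" of one simulated participant. Amplitudes are in
#' uV; the 1/f background has one-sided PSD `pink_scale_uv^2 / f^pink_slope`
#' (uV^2/Hz). `erd_depth` is the fraction by which 8-30 Hz band power drops
#' during movement (amplitude scaled by `sqrt(1 - erd_depth)`).
#'
#' @param alpha_freq_hz Individual alpha frequency (Hz).
#' @param alpha_amp_closed_uv,alpha_amp_open_uv Alpha amplitude with eyes
#'   closed / open (`open < closed`).
#' @param pink_slope Spectral slope gamma of the 1/f background.
#' @param pink_scale_uv Background scale (PSD at 1 Hz is its square).
#' @param blink_rate_hz Mean blink rate during eyes-open (Hz).
#' @param blink_amp_uv Blink peak amplitude on Fp sites (F sites get 1/3).
#' @param erd_depth Fractional 8-30 Hz power drop during movement, [0, 1).
#' @return A list of class `"subject_profile"`.
#' @export
subject_profile <- function(alpha_freq_hz = 10,
                            alpha_amp_closed_uv = 8,
                            alpha_amp_open_uv = 3,
                            pink_slope = 1,
                            pink_scale_uv = 1.1,
                            blink_rate_hz = 0.25,
                            blink_amp_uv = 90,
                            erd_depth = 0.2) {
  stopifnot(alpha_freq_hz > 0, alpha_amp_closed_uv > 0,
            alpha_amp_open_uv >= 0, pink_slope >= 0, pink_scale_uv > 0,
            blink_rate_hz >= 0, blink_amp_uv >= 0)
  if (alpha_amp_open_uv >= alpha_amp_closed_uv) {
    stop("alpha_amp_open_uv must be smaller than alpha_amp_closed_uv")
  }
  if (erd_depth < 0 || erd_depth >= 1) stop("erd_depth must lie in [0, 1)")
  structure(list(alpha_freq_hz = alpha_freq_hz,
                 alpha_amp_closed_uv = alpha_amp_closed_uv,
                 alpha_amp_open_uv = alpha_amp_open_uv,
                 pink_slope = pink_slope, pink_scale_uv = pink_scale_uv,
                 blink_rate_hz = blink_rate_hz, blink_amp_uv = blink_amp_uv,
                 erd_depth = erd_depth),
            class = "subject_profile")
}

#' Synthetic device profile
#'
#' Device-dependent signal components. The garment (textile) profile picks
#' up twice the mains amplitude and amplifies scripted artifacts 2.5x
#' relative to the dry baseline, reflecting its higher contact impedance;
#' the instrumental white-noise floor is the same for both so that
#' resting-state band power below 30 Hz differs only by sampling
#' variability.
#'
#' @param device `"garment"` or `"dry"` (sets defaults), or any name if all
#'   amplitudes are supplied.
#' @param mains_amp_uv 50 Hz mains amplitude (uV).
#' @param artifact_gain Multiplier on scripted artifact amplitudes.
#' @param broadband_noise_uv Instrumental white-noise SD (uV).
#' @param cole Optional [cole_params()] for the matching impedance model.
#' @return A list of class `"device_profile"`.
#' @export
device_profile <- function(device = c("garment", "dry"),
                           mains_amp_uv = NULL, artifact_gain = NULL,
                           broadband_noise_uv = 1.0, cole = NULL) {
  device <- match.arg(device)
  defaults <- list(garment = list(mains = 4.0, gain = 2.5),
                   dry     = list(mains = 2.0, gain = 1.0))[[device]]
  if (is.null(mains_amp_uv)) mains_amp_uv <- defaults$mains
  if (is.null(artifact_gain)) artifact_gain <- defaults$gain
  stopifnot(mains_amp_uv >= 0, artifact_gain >= 0, broadband_noise_uv >= 0)
  structure(list(name = device, mains_amp_uv = mains_amp_uv,
                 artifact_gain = artifact_gain,
                 broadband_noise_uv = broadband_noise_uv, cole = cole),
            class = "device_profile")
}

#' Fixed artifact-induction schedule: nine scripted actions of 10 s each
#' @return A data.frame with columns `label` and `duration_s`.
#' @export
action_schedule <- function() {
  data.frame(label = c("hands_above_head", "tongue", "jaw", "blinking",
                       "eye_movement", "head_vertical", "head_horizontal",
                       "shoulder", "arms"),
             duration_s = 10,
             stringsAsFactors = FALSE)
}

# --- component generators (assume RNG already seeded) -----------------------

# 1/f^slope noise with one-sided PSD scale^2 / f^slope uV^2/Hz.
# Synthesis runs at a highly composite FFT length (R's fft is O(n^2) for
# awkward prime factors) and the first n samples are returned; truncating
# stationary noise leaves its spectrum unchanged.
.gen_pink <- function(n, fs, slope, scale) {
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))
  nh <- floor(n / 2)
  f <- (1:nh) * fs / n
  S <- scale^2 / f^slope
  amp <- sqrt(S * fs * n / 2)
  X <- complex(real = rep(0, n), imaginary = rep(0, n))
  re <- stats::rnorm(nh); im <- stats::rnorm(nh)
  X[2:(nh + 1)] <- amp * complex(real = re, imaginary = im) / sqrt(2)
  if (n %% 2 == 0) {
    X[nh + 1] <- amp[nh] * re[nh]                  # Nyquist bin real
    X[n:(n - nh + 2)] <- Conj(X[2:nh])
  } else {
    X[n:(n - nh + 1)] <- Conj(X[2:(nh + 1)])
  }
  (Re(stats::fft(X, inverse = TRUE)) / n)[seq_len(n_out)]
}

# Correlated 4-channel pink background: shared frontal source + per-channel.
.pink_channels <- function(n, fs, slope, scale, rho = .PINK_RHO) {
  common <- .gen_pink(n, fs, slope, scale)
  out <- matrix(0, 4, n)
  for (ch in 1:4) {
    out[ch, ] <- sqrt(rho) * common +
      sqrt(1 - rho) * .gen_pink(n, fs, slope, scale)
  }
  out
}

# Extract the [lo, hi) Hz component of a vector by FFT masking (zero-padded
# to a composite length; the pad keeps fft fast and only touches the tail).
.band_component <- function(x, fs, lo, hi) {
  n_out <- length(x)
  n <- stats::nextn(n_out, c(2, 3, 5))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  keep <- f >= lo & f < hi
  X <- stats::fft(c(x, numeric(n - n_out)))
  X[!keep] <- 0
  (Re(stats::fft(X, inverse = TRUE)) / n)[seq_len(n_out)]
}

# Slowly varying unit-variance modulation (moving average of white noise).
.slow_am <- function(n, fs, bw_hz = 1) {
  w <- max(3L, as.integer(round(fs / bw_hz)))
  x <- stats::filter(stats::rnorm(n + w), rep(1 / w, w), sides = 1)
  x <- x[(w + 1):(w + n)]
  as.numeric(scale(x))
}

# Raised-cosine pulse train; returns a length-n vector with pulses of
# `width_s` starting at `onsets` (sample indices, 1-based).
.pulse_train <- function(n, fs, onsets, amp, width_s = 0.3) {
  w <- round(width_s * fs)
  pulse <- amp * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = w)))
  out <- numeric(n)
  for (o in onsets) {
    idx <- o:(o + w - 1)
    idx <- idx[idx >= 1 & idx <= n]
    out[idx] <- out[idx] + pulse[seq_along(idx)]
  }
  out
}

# Ocular activity: blink pulses, Fp:F amplitude ratio 3:1.
.blink_matrix <- function(n, fs, rate_hz, amp) {
  out <- matrix(0, 4, n)
  n_blinks <- stats::rpois(1, rate_hz * n / fs)
  if (n_blinks > 0) {
    onsets <- sort(sample.int(max(1L, n - round(0.3 * fs)), n_blinks,
                              replace = TRUE))
    tr <- .pulse_train(n, fs, onsets, amp)
    out[2, ] <- tr; out[3, ] <- tr * stats::runif(1, 0.9, 1.1)
    out[1, ] <- tr / 3; out[4, ] <- tr / 3
  }
  out
}

# Mains pickup: amplitude-modulated 50 Hz line, common across channels with
# small per-channel gain spread.
.mains_matrix <- function(n, fs, amp) {
  if (amp <= 0) return(matrix(0, 4, n))
  tt <- (seq_len(n) - 1) / fs
  line <- (1 + 0.3 * .slow_am(n, fs, bw_hz = 1)) *
    sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
  gains <- stats::runif(4, 0.9, 1.1)
  amp * outer(gains, line)
}

# Shared resting background: pink + alpha rhythm + mains + sensor noise
# (+ blinks when eyes are open).
.background_matrix <- function(profile, device, n, fs, alpha_amp,
                               blinks = FALSE) {
  data <- .pink_channels(n, fs, profile$pink_slope, profile$pink_scale_uv)
  tt <- (seq_len(n) - 1) / fs
  if (alpha_amp > 0) {
    am <- 1 + 0.25 * .slow_am(n, fs, bw_hz = 2)
    wave <- am * sin(2 * pi * profile$alpha_freq_hz * tt +
                       stats::runif(1, 0, 2 * pi))
    gains <- stats::runif(4, 0.8, 1.2)
    data <- data + alpha_amp * outer(gains, wave)
  }
  data <- data + .mains_matrix(n, fs, device$mains_amp_uv)
  data <- data + matrix(stats::rnorm(4 * n, sd = device$broadband_noise_uv),
                        4, n)
  if (blinks && profile$blink_rate_hz > 0) {
    data <- data + .blink_matrix(n, fs, profile$blink_rate_hz,
                                 profile$blink_amp_uv)
  }
  data
}

#' Simulate a resting-state recording
#'
#' Four-channel forehead EEG: 1/f background (inter-channel correlation
#' 0.7), an amplitude-modulated alpha rhythm whose amplitude depends on the
#' eye state, 50 Hz mains pickup scaled by the device profile, instrumental
#' white noise, and (eyes-open only) blink transients dominating the
#' frontopolar channels. Deterministic given `seed`.
#'
#' @param profile A [subject_profile()].
#' @param device A [device_profile()].
#' @param state `"closed"` or `"open"`.
#' @param duration_s Recording length in seconds (default 180, i.e. the
#'   3-minute resting task).
#' @param seed Integer RNG seed.
#' @return An `eeg_recording` with task `ec_rest`/`eo_rest`.
#' @export
simulate_resting <- function(profile, device, state = c("closed", "open"),
                             duration_s = 180, seed = 1) {
  state <- match.arg(state)
  if (duration_s <= 0) stop("duration_s must be positive")
  fs <- .SYNTH_FS
  n <- round(duration_s * fs)
  alpha_amp <- if (state == "closed") profile$alpha_amp_closed_uv else
    profile$alpha_amp_open_uv
  data <- withr::with_seed(seed, {
    .background_matrix(profile, device, n, fs, alpha_amp,
                       blinks = (state == "open"))
  })
  new_recording(data, fs = fs, device = device$name,
                task = if (state == "closed") "ec_rest" else "eo_rest")
}

#' Simulate a cued reaching-movement session
#'
#' Alternating rest (uniform 7 +/- 1 s) and movement (fixed 5 s) periods,
#' by default 4 blocks of 20 movements (80 cues). During movement the
#' entire 8-30 Hz content -- the mu/beta rhythms and the matching slice of
#' the 1/f background -- is scaled by `sqrt(1 - erd_depth)`, so band power
#' drops by the fraction `erd_depth`. A blink plus a brief adjustment
#' burst is inserted at every movement-to-rest transition (participants
#' were free to blink and re-position then). A 3 s lead-in and 2 s tail
#' keep a [-7, 5] s epoch window inside the recording for every cue.
#'
#' @param profile A [subject_profile()].
#' @param device A [device_profile()].
#' @param n_blocks,trials_per_block Session structure (defaults 4 x 20).
#' @param seed Integer RNG seed.
#' @return A list with `recording` (task `"movement"`) and `events` (an
#'   [event_list()] with one `"movement"` entry per cue, duration 5 s).
#' @export
simulate_movement_session <- function(profile, device, n_blocks = 4,
                                      trials_per_block = 20, seed = 1) {
  if (n_blocks < 1 || trials_per_block < 1) {
    stop("n_blocks and trials_per_block must be >= 1")
  }
  fs <- .SYNTH_FS
  n_trials <- n_blocks * trials_per_block
  res <- withr::with_seed(seed, {
    rest_dur <- stats::runif(n_trials, 6, 8)          # 7 +/- 1 s
    move_len <- round(5 * fs)
    lead <- round(3 * fs); tail <- round(2 * fs)
    onsets <- integer(n_trials)                        # 0-based cue samples
    pos <- lead
    for (k in seq_len(n_trials)) {
      pos <- pos + round(rest_dur[k] * fs)
      onsets[k] <- pos
      pos <- pos + move_len
    }
    n <- pos + tail
    tt <- (seq_len(n) - 1) / fs

    # movement gain profile: sqrt(1 - d) while the cue is on
    d <- profile$erd_depth
    g <- rep(1, n)
    for (o in onsets) g[(o + 1):(o + move_len)] <- sqrt(1 - d)

    # 1/f background split at the mu/beta band so only 8-30 Hz desynchronizes
    pink <- .pink_channels(n, fs, profile$pink_slope, profile$pink_scale_uv)
    data <- matrix(0, 4, n)
    for (ch in 1:4) {
      modpart <- .band_component(pink[ch, ], fs, 8, 30)
      data[ch, ] <- (pink[ch, ] - modpart) + g * modpart
    }

    # task rhythms (eyes open, engaged): mu at the alpha frequency + beta
    mu_amp <- profile$alpha_amp_open_uv * 1.5
    beta_amp <- mu_amp * 0.4
    am <- 1 + 0.25 * .slow_am(n, fs, bw_hz = 2)
    mu <- am * sin(2 * pi * profile$alpha_freq_hz * tt +
                     stats::runif(1, 0, 2 * pi))
    beta <- sin(2 * pi * 20 * tt + stats::runif(1, 0, 2 * pi))
    gains <- stats::runif(4, 0.8, 1.2)
    data <- data + outer(gains, g * (mu_amp * mu + beta_amp * beta))

    data <- data + .mains_matrix(n, fs, device$mains_amp_uv)
    data <- data + matrix(stats::rnorm(4 * n, sd = device$broadband_noise_uv),
                          4, n)

    # blink + adjustment artifact at each movement -> rest transition
    trans <- onsets + move_len + 1L
    bl <- .pulse_train(n, fs, trans, profile$blink_amp_uv * 1.2)
    burst_len <- round(0.8 * fs)
    burst <- numeric(n)
    for (o in trans) {
      idx <- o:(o + burst_len - 1); idx <- idx[idx <= n]
      burst[idx] <- burst[idx] + stats::rnorm(length(idx), sd = 10)
    }
    burst <- .band_component(burst, fs, 4, 20) * device$artifact_gain
    data[2, ] <- data[2, ] + bl + burst
    data[3, ] <- data[3, ] + bl + burst
    data[1, ] <- data[1, ] + bl / 3 + burst
    data[4, ] <- data[4, ] + bl / 3 + burst

    list(data = data, onsets = onsets, move_len = move_len)
  })
  rec <- new_recording(res$data, fs = fs, device = device$name,
                       task = "movement")
  ev <- event_list(res$onsets, rep("movement", n_trials),
                   rep(res$move_len, n_trials))
  list(recording = rec, events = ev)
}

# Per-action artifact waveforms (base amplitude, before device gain).
.action_waveform <- function(label, n, fs) {
  band_noise <- function(lo, hi, rms) {
    x <- .band_component(stats::rnorm(n), fs, lo, hi)
    x * rms / stats::sd(x)
  }
  frontal <- function(vec, fp_ratio = 1) {
    rbind(vec / fp_ratio, vec, vec, vec / fp_ratio)
  }
  switch(label,
    hands_above_head = frontal(band_noise(0.5, 3, 60)),
    tongue           = frontal(band_noise(1, 3, 25)) +
                       frontal(band_noise(20, 60, 6)),
    jaw              = frontal(band_noise(20, 90, 18)) +
                       frontal(band_noise(1, 3, 12)),
    blinking         = {
      onsets <- round(seq(0.3, n / fs - 0.5, by = 1) * fs)
      tr <- .pulse_train(n, fs, onsets, 110)
      rbind(tr / 3, tr, tr, tr / 3)
    },
    eye_movement     = {
      steps <- cumsum(sample(c(-1, 1), ceiling(n / fs), replace = TRUE))
      tr <- 55 * rep(steps, each = fs)[1:n]
      tr <- .band_component(tr, fs, 0, 8)    # soften the square edges
      rbind(tr / 3, tr, -tr, -tr / 3)        # lateral dipole pattern
    },
    head_vertical    = frontal(band_noise(0.3, 2, 45)),
    head_horizontal  = frontal(band_noise(0.3, 2, 35)),
    shoulder         = frontal(band_noise(0.5, 4, 25)),
    arms             = frontal(band_noise(0.5, 4, 45)) +
                       frontal(band_noise(20, 60, 8)),
    stop("unknown action '", label, "'")
  )
}

#' Simulate an artifact-induction session
#'
#' Eyes-open resting background plus one scripted artifact waveform per
#' 10 s action segment (broadband motion sway, ocular deflections,
#' EMG-like high-frequency noise, ...), all scaled by the device's
#' `artifact_gain`. Events mark each action segment.
#'
#' @param profile A [subject_profile()].
#' @param device A [device_profile()].
#' @param schedule Action schedule (default [action_schedule()]).
#' @param action_amp_scale Extra multiplier on the scripted waveforms
#'   (0 gives the bare resting background; useful for nulls).
#' @param seed Integer RNG seed.
#' @return A list with `recording` (task `"artifact"`) and `events` (one
#'   entry per action, duration 10 s).
#' @export
simulate_artifact_session <- function(profile, device,
                                      schedule = action_schedule(),
                                      action_amp_scale = 1, seed = 1) {
  if (!all(c("label", "duration_s") %in% names(schedule))) {
    stop("schedule must have columns 'label' and 'duration_s'")
  }
  fs <- .SYNTH_FS
  seg_len <- round(schedule$duration_s * fs)
  n <- sum(seg_len)
  data <- withr::with_seed(seed, {
    bg <- .background_matrix(profile, device, n, fs,
                             profile$alpha_amp_open_uv, blinks = TRUE)
    offset <- 0L
    for (k in seq_len(nrow(schedule))) {
      wav <- .action_waveform(schedule$label[k], seg_len[k], fs)
      cols <- (offset + 1L):(offset + seg_len[k])
      bg[, cols] <- bg[, cols] +
        action_amp_scale * device$artifact_gain * wav
      offset <- offset + seg_len[k]
    }
    bg
  })
  onsets <- cumsum(c(0L, seg_len[-length(seg_len)]))
  rec <- new_recording(data, fs = fs, device = device$name, task = "artifact")
  ev <- event_list(onsets, schedule$label, seg_len)
  list(recording = rec, events = ev)
}

#' Draw a cohort of synthetic subject profiles
#'
#' Profiles are drawn uniformly from documented physiological ranges:
#' alpha frequency 9.5-10.5 Hz, eyes-closed alpha 6-12 uV with an
#' eyes-open fraction of 0.25-0.45, 1/f slope 0.8-1.2, background scale
#' 0.9-1.3 uV, blink rate 0.15-0.35 Hz with 60-120 uV blinks, and
#' movement-related desynchronization depth 0.15-0.35.
#'
#' @param n_subjects Number of profiles (>= 1).
#' @param seed Integer RNG seed.
#' @return A list of [subject_profile()] objects named `S01`, `S02`, ...
#' @export
make_cohort <- function(n_subjects, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  profiles <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      closed <- stats::runif(1, 6, 12)
      subject_profile(
        alpha_freq_hz = stats::runif(1, 9.5, 10.5),
        alpha_amp_closed_uv = closed,
        alpha_amp_open_uv = closed * stats::runif(1, 0.25, 0.45),
        pink_slope = stats::runif(1, 0.8, 1.2),
        pink_scale_uv = stats::runif(1, 0.9, 1.3),
        blink_rate_hz = stats::runif(1, 0.15, 0.35),
        blink_amp_uv = stats::runif(1, 60, 120),
        erd_depth = stats::runif(1, 0.15, 0.35))
    })
  })
  names(profiles) <- sprintf("S%02d", seq_len(n_subjects))
  profiles
}
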