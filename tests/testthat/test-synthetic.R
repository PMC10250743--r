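test_that("generators are exactly reproducible from profile and seed", {
  prof <- subject_profile()
  dev <- device_profile("garment")
  a <- simulate_resting(prof, dev, "open", 20, seed = 5)
  b <- simulate_resting(prof, dev, "open", 20, seed = 5)
  expect_identical(a$data, b$data)
  c <- simulate_resting(prof, dev, "open", 20, seed = 6)
  expect_false(identical(a$data, c$data))

  m1 <- simulate_movement_session(prof, dev, 1, 3, seed = 9)
  m2 <- simulate_movement_session(prof, dev, 1, 3, seed = 9)
  expect_identical(m1$recording$data, m2$recording$data)
  expect_identical(as.data.frame(m1$events), as.data.frame(m2$events))
})

test_that("alpha rhythm reacts to eye state and sits at the alpha peak", {
  prof <- subject_profile()
  dev <- device_profile("dry")
  ec <- compute_psd(bandpass(simulate_resting(prof, dev, "closed", 60,
                                              seed = 3), 0.1, 100))
  eo <- compute_psd(bandpass(simulate_resting(prof, dev, "open", 60,
                                              seed = 3), 0.1, 100))
  expect_gt(band_mean(ec, 8, 12), band_mean(eo, 8, 12))
  # eyes-closed spectrum peaks near 10 Hz within the 5-15 Hz neighbourhood
  sel <- ec$freqs >= 5 & ec$freqs <= 15
  pk <- ec$freqs[sel][which.max(colMeans(ec$log_power)[sel])]
  expect_lt(abs(pk - prof$alpha_freq_hz), 0.75)
})

test_that("without mains the 45-55 Hz band sits at the 1/f background level", {
  prof <- subject_profile()
  quiet <- device_profile("dry", mains_amp_uv = 0, broadband_noise_uv = 0)
  sp <- compute_psd(bandpass(simulate_resting(prof, quiet, "closed", 120,
                                              seed = 8), 0.1, 100))
  sel <- sp$freqs >= 45 & sp$freqs <= 55
  # model background: scale^2 / f^slope, log-averaged over the band bins
  model <- mean(log10(prof$pink_scale_uv^2 / sp$freqs[sel]^prof$pink_slope))
  expect_lt(abs(band_mean(sp, 45, 55) - model), 0.1)   # within 1 dB
})

test_that("background spectral slope tracks the profile within 0.3", {
  for (slope in c(0.8, 1.2)) {
    prof <- subject_profile(pink_slope = slope, alpha_amp_closed_uv = 0.01,
                            alpha_amp_open_uv = 0.001)
    quiet <- device_profile("dry", mains_amp_uv = 0, broadband_noise_uv = 0)
    sp <- compute_psd(bandpass(simulate_resting(prof, quiet, "closed", 120,
                                                seed = 13), 0.1, 100))
    sel <- sp$freqs >= 2 & sp$freqs <= 40
    fit <- stats::lm(colMeans(sp$log_power)[sel] ~ log10(sp$freqs[sel]))
    expect_lt(abs(unname(stats::coef(fit)[2]) + slope), 0.3)
  }
})

test_that("movement sessions emit the cued-trial structure", {
  sess <- simulate_movement_session(subject_profile(),
                                    device_profile("dry"), seed = 2)
  expect_equal(nrow(sess$events), 80)                 # 4 blocks x 20
  expect_true(all(sess$events$label == "movement"))
  expect_true(all(sess$events$duration_samples == 5 * 256))
  gaps <- diff(sess$events$onset_sample) - 5 * 256    # rest durations
  expect_true(all(gaps >= 6 * 256 - 1 & gaps <= 8 * 256 + 1))
  # every [-7, 5] s epoch fits
  expect_gte(min(sess$events$onset_sample), 7 * 256)
})

test_that("zero erd_depth leaves the movement window unmodulated", {
  prof <- subject_profile(erd_depth = 0)
  sess <- simulate_movement_session(prof, device_profile("dry"),
                                    n_blocks = 3, trials_per_block = 10,
                                    seed = 21)
  rec <- bandpass(sess$recording, 0.3, 30)
  ep <- extract_epochs(rec, sess$events, "movement", -7, 5)
  tfr <- morlet_tfr(ep, 8, 12, 0.5, decim = 8)
  avg <- grand_average_erds(erds(tfr))
  sel_t <- avg$times >= 0.5 & avg$times <= 4.5
  expect_lt(abs(mean(avg$map[, sel_t])), 5)
})

test_that("artifact sessions mark nine 10 s actions and amplify with gain", {
  prof <- subject_profile()
  g <- simulate_artifact_session(prof, device_profile("garment"), seed = 14)
  d <- simulate_artifact_session(prof, device_profile("dry"), seed = 14)
  expect_equal(nrow(g$events), 9)
  expect_true(all(g$events$duration_samples == 2560))
  expect_equal(g$events$label, action_schedule()$label)

  # same seed: garment broadband (0-30 Hz) power strictly higher in every
  # action segment (artifact gain 2.5 vs 1 on identical waveforms)
  for (k in 1:9) {
    cols <- (g$events$onset_sample[k] + 1):(g$events$onset_sample[k] + 2560)
    pg <- band_mean(compute_psd(new_recording(g$recording$data[, cols], 256)),
                    0, 30)
    pd <- band_mean(compute_psd(new_recording(d$recording$data[, cols], 256)),
                    0, 30)
    expect_gt(pg, pd)
  }
})

test_that("zero-amplitude schedule reduces to the resting background", {
  prof <- subject_profile()
  dev <- device_profile("dry")   # artifact_gain 1
  art <- simulate_artifact_session(prof, dev, action_amp_scale = 0,
                                   seed = 17)
  bg <- simulate_resting(prof, dev, "open", duration_s = 90, seed = 17)
  expect_equal(art$recording$data, bg$data)
})

test_that("cohorts are reproducible and within documented ranges", {
  c1 <- make_cohort(10, seed = 4)
  c2 <- make_cohort(10, seed = 4)
  expect_identical(c1, c2)
  c3 <- make_cohort(10, seed = 5)
  expect_false(identical(c1, c3))
  for (p in c1) {
    expect_true(p$alpha_freq_hz >= 9.5 && p$alpha_freq_hz <= 10.5)
    expect_true(p$alpha_amp_open_uv < p$alpha_amp_closed_uv)
    expect_true(p$erd_depth >= 0.15 && p$erd_depth <= 0.35)
    expect_true(p$pink_slope >= 0.8 && p$pink_slope <= 1.2)
  }
})

test_that("device contrast: garment beats dry at 45-55 Hz for every subject", {
  cohort <- make_cohort(6, seed = 6)
  set.seed(99)
  seeds <- matrix(sample(1e6, 12), 6, 2)
  for (s in seq_along(cohort)) {
    g <- compute_psd(bandpass(simulate_resting(cohort[[s]],
                                               device_profile("garment"),
                                               "open", 60,
                                               seed = seeds[s, 1]),
                              0.1, 100))
    d <- compute_psd(bandpass(simulate_resting(cohort[[s]],
                                               device_profile("dry"),
                                               "open", 60,
                                               seed = seeds[s, 2]),
                              0.1, 100))
    expect_gt(band_mean(g, 45, 55), band_mean(d, 45, 55))
  }
})
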