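test_that("Welch grid, floor and tone localization behave as specified", {
  fs <- 256
  set.seed(1)
  tt <- (0:(60 * fs - 1)) / fs
  x <- 20 * sin(2 * pi * 10 * tt) + rnorm(length(tt), sd = 0.5)
  sp <- compute_psd(new_recording(rbind(x, x, x, x), fs))
  expect_equal(unique(round(diff(sp$freqs), 10)), 0.25)
  expect_equal(max(sp$freqs), 60)
  expect_equal(sp$freqs[which.max(sp$log_power[1, ])], 10)

  zero <- compute_psd(new_recording(matrix(0, 4, 10 * fs), fs))
  expect_true(all(zero$log_power == log10(1e-20)))

  short <- new_recording(matrix(rnorm(4 * 100), 4), fs)
  expect_error(compute_psd(short), "length error")
})

test_that("PSD is channel-order invariant and quadratic in amplitude", {
  rec <- simulate_resting(subject_profile(), device_profile("dry"),
                          "closed", 30, seed = 41)
  sp <- compute_psd(rec)
  rec_flip <- rec
  rec_flip$data <- rec$data[4:1, ]
  rec_flip$channel_names <- rec$channel_names[4:1]
  sp_flip <- compute_psd(rec_flip)
  expect_equal(unname(sp$log_power[1, ]), unname(sp_flip$log_power[4, ]))

  rec2 <- rec
  rec2$data <- rec$data * 2
  sp2 <- compute_psd(rec2)
  expect_equal(sp2$log_power - sp$log_power,
               matrix(log10(4), nrow(sp$log_power), ncol(sp$log_power)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("white noise has flat band means across delta-beta", {
  set.seed(2)
  rec <- new_recording(matrix(rnorm(4 * 256 * 120), 4), 256)
  sp <- compute_psd(rec)
  cfg <- analysis_config()
  bands <- vapply(cfg$bands[c("delta", "theta", "alpha", "beta")],
                  function(b) band_mean(sp, b[1], b[2]), 0)
  expect_lt(max(bands) - min(bands), 0.1)            # within 1 dB
})

test_that("band power table averages electrodes then in-band bins", {
  freqs <- c(1, 2, 3, 4)
  # 3 channels, hand-computed two-bin band
  lp <- rbind(c(0, 1, 2, 3), c(1, 2, 3, 4), c(2, 3, 4, 5))
  sp <- toy_spectrum(lp, freqs)
  cfg <- analysis_config(bands = list(lo = c(1, 2), hi = c(3, 4)))
  tab <- band_power_table(list(sp), cfg)
  expect_equal(tab$lo, mean(c(mean(lp[, 1]), mean(lp[, 2]))))
  expect_equal(tab$hi, mean(c(mean(lp[, 3]), mean(lp[, 4]))))

  flat <- toy_spectrum(matrix(2.5, 4, 4), freqs)
  tabf <- band_power_table(list(flat), cfg)
  expect_equal(tabf$lo, 2.5)
  expect_equal(tabf$hi, 2.5)

  # a 10 Hz line dominates alpha only
  freqs2 <- seq(0, 60, by = 0.25)
  lp2 <- matrix(-2, 4, length(freqs2))
  lp2[, freqs2 == 10] <- 3
  tab2 <- band_power_table(list(toy_spectrum(lp2, freqs2)),
                           analysis_config())
  expect_true(tab2$alpha > max(tab2$delta, tab2$theta, tab2$beta, tab2$mains))

  # grid mismatch
  expect_error(band_power_table(list(sp, toy_spectrum(lp, freqs + 0.5)),
                                cfg),
               "alignment error")
})

test_that("band edges are inclusive and adjacent bands share no bins", {
  freqs <- seq(0, 60, by = 0.25)
  lp <- matrix(0, 4, length(freqs))
  lp[, freqs == 3] <- 10       # exactly on the delta upper edge
  tab <- band_power_table(list(toy_spectrum(lp, freqs)), analysis_config())
  expect_gt(tab$delta, 0)
  expect_equal(tab$theta, 0)
})

test_that("artifact recordings segment into labelled 10 s actions", {
  sess <- simulate_artifact_session(subject_profile(),
                                    device_profile("dry"), seed = 15)
  segs <- segment_by_action(sess$recording, sess$events)
  expect_length(segs, 9)
  expect_true(all(vapply(segs, function(s) ncol(s$data), 0) == 2560))
  expect_equal(vapply(segs, function(s) s$action, ""),
               stats::setNames(action_schedule()$label,
                               action_schedule()$label))

  expect_equal(segment_by_action(sess$recording,
                                 event_list(integer(), character(),
                                            integer())),
               list())
  bad <- event_list(c(0, 1000), c("a", "b"), c(2000, 2560))
  expect_error(segment_by_action(sess$recording, bad), "overlapping")
  over <- event_list(ncol(sess$recording$data) - 100, "a", 2560)
  expect_error(segment_by_action(sess$recording, over), "past the end")
})

test_that("device comparison pairs subjects and reports direction", {
  subj <- sprintf("S%02d", 1:10)
  tab <- data.frame(subject = rep(subj, 2),
                    device = rep(c("garment", "dry"), each = 10),
                    task = "ec_rest", action = NA,
                    alpha = c(rnorm(10), rnorm(10)))
  tab$alpha[1:10] <- tab$alpha[11:20]          # identical -> degenerate
  r <- compare_devices_by_band(tab, "alpha", "ec_rest")
  expect_equal(r$p, 1)

  tab$alpha[1:10] <- tab$alpha[11:20] + 1.0
  r2 <- compare_devices_by_band(tab, "alpha", "ec_rest")
  expect_equal(r2$p, 2 / 2^10)
  expect_equal(r2$direction, 1)

  expect_error(compare_devices_by_band(tab[-1, ], "alpha", "ec_rest"),
               "pairing error")
})
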