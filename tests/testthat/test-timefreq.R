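test_that("Morlet power localizes tones and scales quadratically", {
  fs <- 256
  tt <- seq(-3, 3, by = 1 / fs)
  x <- sin(2 * pi * 15 * tt)
  ep <- toy_epochs(array(x, dim = c(1, 1, length(tt))), fs, tmin = -3)
  tf <- morlet_tfr(ep, 5, 30, 0.25)
  prof <- apply(tf$power[1, 1, , ], 1, mean)
  expect_lte(abs(tf$freqs[which.max(prof)] - 15), 0.25)
  expect_equal(dim(tf$power)[3], 101)                  # 5-30 at 0.25 Hz

  ep2 <- ep
  ep2$data <- ep$data * 2
  tf2 <- morlet_tfr(ep2, 5, 30, 0.25)
  expect_equal(tf2$power, 4 * tf$power, tolerance = 1e-12)

  zed <- toy_epochs(array(0, dim = c(2, 1, length(tt))), fs, tmin = -3)
  expect_true(all(morlet_tfr(zed, 5, 30, 1)$power == 0))

  tiny <- toy_epochs(array(rnorm(2 * 1 * 100), dim = c(2, 1, 100)), fs)
  expect_error(morlet_tfr(tiny, 5, 30, 1), "length error")
})

test_that("edge samples within a wavelet half-length are flagged", {
  fs <- 256
  ep <- toy_epochs(array(rnorm(2 * 1 * 4 * fs), dim = c(2, 1, 4 * fs)),
                   fs, tmin = -2)
  tf <- morlet_tfr(ep, 5, 30, 5)
  half5 <- ceiling(5 * 7 / (2 * pi * 5) * fs)
  expect_true(all(tf$edges[1, seq_len(half5)]))
  expect_false(any(tf$edges[1, (half5 + 1):(4 * fs - half5)]))
  # higher frequencies have shorter wavelets, hence narrower edges
  expect_lt(sum(tf$edges[nrow(tf$edges), ]), sum(tf$edges[1, ]))
})

test_that("ERD/ERS maps implement percent change vs the pre-cue baseline", {
  # hand-built TFR: power 2 before t=0, 1 after, at all frequencies
  times <- seq(-6, 5, by = 0.25)
  freqs <- seq(8, 12, by = 1)
  pw <- array(0, dim = c(3, 2, length(freqs), length(times)))
  pw[, , , times < 0] <- 2
  pw[, , , times >= 0] <- 1
  tfr <- structure(list(power = pw, freqs = freqs, times = times, fs = 256,
                        channel_names = c("F7", "Fp1"),
                        edges = matrix(FALSE, length(freqs), length(times)),
                        n_cycles = 7),
                   class = "eeg_tfr")
  maps <- erds(tfr, c(-5, -2))
  expect_length(maps, 2)
  m <- maps[[1]]$map
  expect_true(all(abs(m[, times >= 0] + 50) < 1e-9))   # exactly -50%
  bl <- times >= -5 & times <= -2
  expect_true(all(abs(rowMeans(m[, bl])) < 1e-9))      # baseline averages 0
  expect_true(all(m >= -100))

  expect_error(erds(tfr, c(-20, -10)), "baseline interval outside")
  tfr0 <- tfr
  tfr0$power[, , 2, ] <- 0
  expect_error(erds(tfr0, c(-5, -2)), "degenerate baseline")
})

test_that("grand averaging is the arithmetic mean in the stated order", {
  m1 <- toy_map(matrix(10, 4, 5))
  m2 <- toy_map(matrix(-10, 4, 5))
  expect_equal(grand_average_erds(list(m1, m1))$map, m1$map)
  expect_equal(grand_average_erds(list(m1, m2))$map, matrix(0, 4, 5))

  # trial-then-electrode averaging equals the direct mean for equal trial
  # counts: erds() averages trials internally, so averaging the per-channel
  # maps matches averaging a single pooled map built from the same power
  set.seed(8)
  times <- seq(-6, 2, by = 0.5)
  pw <- array(stats::runif(6 * 2 * 3 * length(times), 1, 2),
              dim = c(6, 2, 3, length(times)))
  tfr <- structure(list(power = pw, freqs = 1:3, times = times, fs = 256,
                        channel_names = c("a", "b"),
                        edges = matrix(FALSE, 3, length(times)),
                        n_cycles = 7),
                   class = "eeg_tfr")
  per_ch <- erds(tfr, c(-5, -2))
  avg_map <- grand_average_erds(per_ch)$map
  manual <- (per_ch[[1]]$map + per_ch[[2]]$map) / 2
  expect_equal(avg_map, manual)

  bad <- toy_map(matrix(0, 4, 5), freqs = 2:5)
  expect_error(grand_average_erds(list(m1, bad)), "alignment error")
})

test_that("bin-wise comparison masks by paired significance", {
  set.seed(12)
  mk <- function(shift = 0) {
    lapply(1:10, function(i) toy_map(matrix(rnorm(50), 5, 10) + shift))
  }
  same <- mk()
  r <- binwise_device_comparison(same, same)
  expect_false(any(r$mask))                    # all-zero differences
  expect_true(all(r$masked_diff == 0))

  g <- mk()
  d <- lapply(g, function(m) toy_map(m$map - 20))
  r2 <- binwise_device_comparison(g, d)
  expect_true(all(r2$mask))                    # p = 2/1024 < 0.05 each bin
  expect_equal(r2$diff, matrix(-20, 5, 10))
  expect_equal(r2$masked_diff, matrix(-20, 5, 10))

  # mask monotone in alpha
  g2 <- mk(); d2 <- mk()
  r05 <- binwise_device_comparison(g2, d2, alpha = 0.05)
  r01 <- binwise_device_comparison(g2, d2, alpha = 0.01)
  expect_true(all(which(r01$mask) %in% which(r05$mask)))

  expect_error(binwise_device_comparison(g[1:3], d), "pairing error")
  expect_error(binwise_device_comparison(g[1], d[1]), "at least 2")
})
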