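test_that("Cole magnitude has the closed-form limits and hand value", {
  p <- cole_params(R_s = 1000, R_p = 5000, tau = 0.16, alpha = 0.8)
  expect_equal(cole_magnitude(p, 1e-9), 6000, tolerance = 1e-4)
  expect_equal(cole_magnitude(p, 1e9), 1000, tolerance = 1e-3)

  # alpha = 1 at the corner frequency f = 1/(2 pi tau):
  # |Z| = |R_s + R_p / (1 + i)|
  p1 <- cole_params(R_s = 1000, R_p = 5000, tau = 0.16, alpha = 1)
  f_c <- 1 / (2 * pi * 0.16)
  hand <- Mod(1000 + 5000 / (1 + 1i))
  expect_equal(cole_magnitude(p1, f_c), hand, tolerance = 1e-9)

  expect_error(cole_magnitude(p, 0), "positive")
})

test_that("Cole magnitude decreases strictly with frequency", {
  for (a in c(0.5, 0.8, 1)) {
    p <- cole_params(R_s = 2000, R_p = 80000, tau = 0.16, alpha = a)
    sweep <- cole_magnitude(p, 10^seq(-2, 3, length.out = 200))
    expect_true(all(diff(sweep) < 0))
  }
})

test_that("calibration reproduces the measured anchors for all technologies", {
  anchors <- list(garment = c(368e3, 171e3),
                  dry = c(110e3, 78e3),
                  wet = c(3.2e3, 3.05e3))
  for (tech in names(anchors)) {
    a <- anchors[[tech]]
    p <- calibrate_profile(a[1], a[2])
    expect_lt(abs(cole_magnitude(p, 1) - a[1]) / a[1], 0.005)
    expect_lt(abs(cole_magnitude(p, 10) - a[2]) / a[2], 0.005)
  }
  # wet is nearly flat: dispersion is a small fraction of the total
  pw <- calibrate_profile(3.2e3, 3.05e3)
  expect_lt(pw$R_p / (pw$R_s + pw$R_p), 0.15)

  # degenerate equal anchors collapse to a flat curve
  pf <- calibrate_profile(1e4, 1e4)
  expect_equal(pf$R_p, 0)
  expect_equal(cole_magnitude(pf, 0.5), 1e4)

  expect_error(calibrate_profile(100, 200), "argument error")
})

test_that("simulated study has the 6x4x3 design and converges to anchors", {
  m <- simulate_impedance_study(seed = 3)
  expect_equal(nrow(m), 3 * 6 * 4 * 3 * 10)      # tech x subj x elec x rep x freqs
  per_tech <- table(m$technology) / 10
  expect_true(all(per_tech == 72))
  expect_identical(m, simulate_impedance_study(seed = 3))

  # zero spread reproduces the model curve exactly
  m0 <- simulate_impedance_study(
    params_by_tech = list(dry = calibrate_profile(110e3, 78e3,
                                                  sigma_log = 0)),
    point_jitter = 0, seed = 5)
  base <- cole_magnitude(calibrate_profile(110e3, 78e3), impedance_grid())
  expect_equal(m0$z_ohm, rep(base, 72), tolerance = 1e-12)

  # 72-measurement mean at 1 Hz near the garment anchor
  avg <- average_impedance(m, "garment")
  expect_lt(abs(impedance_at(avg, 1) - 368e3) / 368e3, 0.05)
})

test_that("curve averaging matches manual mean/SEM and ignores order", {
  freqs <- impedance_grid()
  mk <- function(subject, z) data.frame(technology = "dry",
                                        subject = subject, electrode = "F7",
                                        repetition = 1, freq_hz = freqs,
                                        z_ohm = z)
  z1 <- 1000 * (1:10); z2 <- 2000 * (1:10); z3 <- 1500 * (1:10)
  m <- rbind(mk("a", z1), mk("b", z2), mk("c", z3))
  avg <- average_impedance(m, "dry")
  expect_equal(avg$z_mean, (z1 + z2 + z3)[order(freqs)] / 3)
  manual_sem <- vapply(seq_len(10), function(i) sem(c(z1[i], z2[i], z3[i])), 0)
  expect_equal(avg$z_sem, manual_sem[order(freqs)])

  perm <- m[sample(nrow(m)), ]
  expect_equal(average_impedance(perm, "dry"), avg)

  ident <- rbind(mk("a", z1), mk("b", z1))
  expect_true(all(average_impedance(ident, "dry")$z_sem == 0))

  bad <- rbind(mk("a", z1),
               within(mk("b", z2), freq_hz <- freq_hz * 1.01))
  expect_error(average_impedance(bad, "dry"), "alignment error")
})

test_that("log-log interpolation is exact on grid hits and power laws", {
  freqs <- impedance_grid()
  curve <- data.frame(freq_hz = freqs, z_mean = 1e5 / freqs)  # |Z| ~ 1/f
  expect_equal(impedance_at(curve, freqs[4]), 1e5 / freqs[4])
  for (f in c(0.5, 2.3, 17)) {
    expect_equal(impedance_at(curve, f), 1e5 / f, tolerance = 1e-10)
  }
  expect_error(impedance_at(curve, 50), "extrapolation error")
})

test_that("threshold verdicts separate wet from dry technologies", {
  freqs <- impedance_grid()
  profs <- default_cole_profiles()
  wet <- data.frame(freq_hz = freqs,
                    z_mean = cole_magnitude(profs$wet, freqs))
  expect_true(below_threshold(wet)$overall)
  garment <- data.frame(freq_hz = freqs,
                        z_mean = cole_magnitude(profs$garment, freqs))
  expect_false(below_threshold(garment)$overall)
  flat <- data.frame(freq_hz = freqs, z_mean = rep(5000, 10))
  expect_false(below_threshold(flat)$overall)   # strict inequality
})
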