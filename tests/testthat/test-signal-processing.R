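test_that("partial-volume scale interpolates between CSF and tissue", {
  expect_equal(pv_scale(1000, 500, 500), 1)          # pure CSF voxel
  expect_equal(pv_scale(1000, 500, 1000), 2)         # pure tissue: tiss/csf
  expect_equal(pv_scale(1000, 500, 750), 1.5)        # halfway
  # m >= 1 throughout [csf, tissue], equality only at pure CSF
  vox <- seq(500, 1000, by = 25)
  m <- pv_scale(1000, 500, vox)
  expect_true(all(m >= 1))
  expect_equal(sum(m == 1), 1L)
  expect_error(pv_scale(500, 500, 500), "t1w_tiss > t1w_csf")
})

test_that("fMRI preprocessing trims, baselines, and filters", {
  expect_equal(length(preprocess_fmri(rep(5, 240), tr = 0.5)), 200L)
  # constant series is zeroed by the baseline step
  expect_equal(preprocess_fmri(rep(5, 100), tr = 0.5, lowpass = NULL),
               rep(0, 60))
  expect_error(preprocess_fmri(rnorm(30), tr = 0.5), "shorter")
  # 1 Hz attenuated by >= 20 dB relative to 0.1 Hz (fs = 4 Hz, cutoff 0.5)
  t <- seq(0, 200, by = 0.25)
  resp <- function(f) {
    y <- butter_lowpass <- csfinflow:::butter_lowpass(sin(2 * pi * f * t),
                                                      fs = 4, cutoff = 0.5)
    max(abs(y[t > 20 & t < 180]))
  }
  expect_gt(20 * log10(resp(0.1) / resp(1)), 20)
})

test_that("second preprocessing pass only removes the trim", {
  set.seed(1)
  x <- 10 + cumsum(rnorm(300, 0, 0.05))
  once <- preprocess_fmri(x, tr = 0.5, lowpass = NULL)
  twice <- preprocess_fmri(once, tr = 0.5, lowpass = NULL)
  # the trim shortens; the baseline shift is already near zero
  expect_equal(length(twice), length(once) - 40L)
  expect_equal(twice, once[-seq_len(40)] - mean(sort(once[-seq_len(40)])[
    seq_len(ceiling(0.1 * (length(once) - 40)))]), tolerance = 1e-12)
})

test_that("phase contrast converts offset-corrected phase by VENC / pi", {
  phi_s <- rep(0.2, 50)
  expect_equal(phase_to_velocity(phi_s, phi_s, venc = 6), rep(0, 50))
  expect_equal(phase_to_velocity(rep(0.2 + pi, 5), rep(0.2, 5), venc = 6),
               rep(6, 5))
  # linear in the corrected phase
  phi <- runif(20, -1, 1)
  expect_equal(phase_to_velocity(2 * phi, rep(0, 20), 6),
               2 * phase_to_velocity(phi, rep(0, 20), 6))
  expect_error(phase_to_velocity(1:3, 1:4, 6), "equal length")
})

test_that("peak detection honours prominence and separation", {
  t <- seq(0, 60, by = 0.1)
  x <- sin(2 * pi * t / 6)
  pk <- find_signal_peaks(x, distance = 50, prominence = 0.1)
  expect_equal(length(pk), 10L)
  expect_equal(unique(round(diff(pk) * 0.1, 6)), 6)
  # a small bump below the prominence threshold is rejected
  x2 <- x + 0.03 * sin(2 * pi * t / 0.8)
  pk2 <- find_signal_peaks(x2, distance = 50, prominence = 0.1)
  expect_equal(length(pk2), 10L)
})

test_that("cycle averaging recovers one period and rejects short cycles", {
  dt <- 0.25
  t <- seq(0, 120, by = dt)
  x <- sin(2 * pi * t / 6)
  ca <- cycle_average(x, dt, expected_period = 6)
  expect_equal(ca$n_cycles, floor(120 / 6) - 1L)
  expect_equal(ca$period_estimate, 6, tolerance = 0.02)
  # the mean cycle is a single period: endpoints at the peak value
  expect_equal(ca$cycle[1], 1, tolerance = 0.01)
  expect_equal(max(ca$cycle) - min(ca$cycle), 2, tolerance = 0.05)
  # insert one 4-s cycle: its peak is rejected by the 5-s separation rule
  tA <- seq(0, 36, by = dt); tB <- seq(0, 4 - dt, by = dt)
  tC <- seq(0, 36, by = dt)
  xi <- c(sin(2 * pi * tA / 6), sin(2 * pi * tB / 4), sin(2 * pi * tC / 6))
  ca2 <- cycle_average(xi, dt, expected_period = 6)
  expect_lt(ca2$n_cycles, floor(length(xi) * dt / 6))
  expect_error(cycle_average(x[1:20], dt, 6), "two expected periods")
})

test_that("cycle averaging is phase invariant and averages down noise", {
  dt <- 0.25
  t <- seq(0, 120, by = dt)
  base <- cycle_average(sin(2 * pi * t / 6), dt, 6)
  shifted <- cycle_average(sin(2 * pi * (t + 2.1) / 6), dt, 6)
  expect_equal(base$n_cycles, shifted$n_cycles)
  expect_equal(base$period_estimate, shifted$period_estimate, tolerance = 0.02)
  # shapes agree up to the peak-location quantization of the upsampled grid
  # (peaks are located on the interpolated grid, so the recording phase can
  # shift the locked cycle by up to one coarse sample)
  aligns <- vapply(-4:4, function(l) {
    idx <- ((seq_along(base$cycle) - 1 + l) %% length(base$cycle)) + 1
    max(abs(base$cycle[idx] - shifted$cycle))
  }, 0)
  expect_lt(min(aligns), 0.05)  # sub-sample residual remains
  # Monte-Carlo: residual noise variance shrinks roughly like 1 / n_cycles
  set.seed(9)
  resid <- replicate(30, {
    x <- sin(2 * pi * t / 6) + rnorm(length(t), 0, 0.2)
    ca <- cycle_average(x, dt, 6)
    stats::var(ca$cycle - base$cycle)
  })
  expect_lt(mean(resid), 0.2^2 / base$n_cycles * 3)
})

test_that("cycle error is a symmetric mean absolute difference", {
  a <- sin(seq(0, 2 * pi, length.out = 50))
  expect_equal(cycle_error(a, a), 0)
  expect_equal(cycle_error(a, a + 0.05), 0.05, tolerance = 1e-9)
  b <- cos(seq(0, 2 * pi, length.out = 80))
  expect_equal(cycle_error(a, b), cycle_error(b, a), tolerance = 1e-9)
})

test_that("Welch spectra localize tones and satisfy Parseval", {
  fs <- 10
  t <- seq(0, 200 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.8 * t)
  ps <- spectral_density(x, fs, nperseg = 512)
  expect_equal(ps$freqs[which.max(ps$psd)], 0.8, tolerance = 0.02)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_equal(sum(ps$psd) * df, stats::var(x), tolerance = 0.05)
  # white noise: flat within Monte-Carlo tolerance
  set.seed(21)
  w <- rnorm(20000)
  pw <- spectral_density(w, fs, nperseg = 256)
  band_lo <- mean(pw$psd[pw$freqs < 2.5 & pw$freqs > 0.1])
  band_hi <- mean(pw$psd[pw$freqs > 2.5])
  expect_equal(band_lo / band_hi, 1, tolerance = 0.1)
  expect_equal(sum(pw$psd) * (pw$freqs[2] - pw$freqs[1]), stats::var(w),
               tolerance = 0.05)
})

test_that("power-law fit recovers known exponents", {
  f <- seq(0.05, 1, by = 0.01)
  expect_equal(power_law_fit(f, f^(-2), c(0.05, 1)), -2, tolerance = 1e-9)
  expect_equal(power_law_fit(f, rep(3, length(f)), c(0.05, 1)), 0,
               tolerance = 1e-9)
  expect_error(power_law_fit(f, -f, c(0.05, 1)), "positive")
})

test_that("relative bandpower isolates the paced-breathing band", {
  fs <- 2
  t <- seq(0, 300, by = 1 / fs)
  expect_gt(relative_bandpower(sin(2 * pi * 0.167 * t), fs), 0.9)
  expect_lt(relative_bandpower(sin(2 * pi * 0.5 * t), fs), 0.05)
  # white noise: expected fraction ~ band width / Nyquist bandwidth
  set.seed(31)
  fr <- replicate(40, relative_bandpower(rnorm(600), fs))
  expect_lt(abs(mean(fr) - 0.05 / 1), 0.015)
})

test_that("areas from labeled volumes follow the intensity scaling rule", {
  lab <- array(0L, c(4, 5, 3))
  t1w <- array(100, c(4, 5, 3))
  lab[1:2, 1:5, 1] <- 1L   # 10 voxels in slice 1
  lab[1:2, 1:5, 2] <- 1L
  t1w[1, 1, 2] <- 200      # one labeled voxel at twice the slice minimum
  vox <- c(0.1, 0.1, 0.25) # 0.01 cm^2 in-plane
  prof <- area_from_labels(lab, t1w, vox)
  expect_equal(prof$areas[1], 0.1)                   # uniform slice
  expect_equal(prof$areas[2], 0.09 + 0.01 * 0.5)     # half contribution
  # doubling all intensities changes nothing (ratio invariance)
  prof2 <- area_from_labels(lab, t1w * 2, vox)
  expect_equal(prof2$areas, prof$areas)
  expect_equal(diff(prof$positions), 0.25)
})
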