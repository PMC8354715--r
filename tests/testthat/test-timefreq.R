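test_that("periodogram recovers sinusoid power, zero signal, and Parseval's identity", {
  ep <- make_sine_epochs(freq = 10, n_trials = 3, n_channels = 1, amp = 4,
                         window = c(-1, 1))
  sp <- periodogram_mean(ep, window = c(-1, 0), channels = 1)
  peak <- which.max(sp$power)
  expect_equal(sp$frequencies[peak], 10)
  expect_equal(sp$power[peak], 4^2 / 4, tolerance = 1e-9)

  zero <- eeg_epochs(array(0, c(2, 1, 1000)),
                     seq(-1, 1 - 1 / 500, by = 1 / 500), 500,
                     channel_labels = "z")
  expect_true(all(periodogram_mean(zero, window = c(-1, 0))$power == 0))

  set.seed(8)
  ep2 <- make_sine_epochs(freq = 7, n_trials = 1, n_channels = 1,
                          noise_sd = 3, window = c(-1, 1))
  sp2 <- periodogram_mean(ep2, window = c(-1, 0), channels = 1)
  x <- ep2$data[1, 1, ep2$time_axis >= -1 & ep2$time_axis < 0]
  expect_equal(sum(sp2$power_full), mean(x^2), tolerance = 1e-6)
})

test_that("bipolar periodogram channels select the difference of two channels", {
  set.seed(9)
  ep <- make_sine_epochs(freq = 6, n_trials = 2, n_channels = 2,
                         channel_phase = c(0, pi), window = c(-1, 1))
  sp2 <- periodogram_mean(ep, window = c(-1, 0), channels = c("ch1", "ch2"))
  # difference of antiphase unit sinusoids = amplitude-2 sinusoid
  expect_equal(max(sp2$power), 2^2 / 4, tolerance = 1e-9)
})

test_that("spectral exponent is the log-log slope and is scale invariant", {
  f <- seq(1, 60, by = 0.25)
  mk <- function(p) structure(list(frequencies = f, power = p), class = "eeg_spectrum")
  expect_equal(spectral_exponent(mk(rep(3, length(f)))), 0, tolerance = 1e-12)
  expect_equal(spectral_exponent(mk(f^-2)), -2, tolerance = 1e-9)
  expect_equal(spectral_exponent(mk(5 * f^-2)), -2, tolerance = 1e-9)
  expect_error(spectral_exponent(mk(f - 30)), "nonpositive")
  expect_error(spectral_exponent(mk(f^-1), band = c(20, 20.3)), "3 frequency bins")
})

test_that("spectral exponent of inverse-FFT shaped noise is recovered", {
  # independent shaping code (not the session generator), shaped on the exact
  # analysis-window grid so every component sits on a DFT bin
  rate <- 500; nw <- 2000; nt <- 2100
  t <- seq(-4, 0.2 - 1 / rate, by = 1 / rate)
  fax <- pmin(0:(nw - 1), nw - (0:(nw - 1))) * rate / nw
  shape <- c(0, fax[-1]^(-3 / 2))
  set.seed(10)
  d <- array(0, c(90, 1, nt))
  for (r in 1:90)
    d[r, 1, 1:nw] <- Re(fft(fft(rnorm(nw)) * shape, inverse = TRUE)) / nw
  ep <- eeg_epochs(d, t, rate, channel_labels = "bg")
  sp <- periodogram_mean(ep, window = c(-4, 0), channels = 1)
  expect_equal(spectral_exponent(sp), -3, tolerance = 0.15)
})

test_that("Morlet decomposition localizes a sinusoid and matches direct convolution", {
  ep <- make_sine_epochs(freq = 10, n_trials = 2, n_channels = 1,
                         window = c(-1, 1))
  tf <- morlet_tf(ep, freqs = 5:20)
  mid <- which.min(abs(tf$times))
  pw <- Mod(tf$coef[1, 1, , mid])
  expect_equal(tf$freqs[which.max(pw)], 10)
  expect_equal(max(pw), 1, tolerance = 1e-3)

  # constant input phase offset leaves interior magnitudes unchanged
  # (edge samples see a truncated wavelet and are excluded)
  ep2 <- make_sine_epochs(freq = 10, n_trials = 2, n_channels = 1,
                          phases = rep(pi / 3, 2), window = c(-1, 1))
  tf2 <- morlet_tf(ep2, freqs = 5:20)
  interior <- which(abs(tf$times) <= 0.5)
  k10 <- which(tf$freqs == 10)
  expect_equal(Mod(tf2$coef[, , k10, interior]), Mod(tf$coef[, , k10, interior]),
               tolerance = 1e-3)
  # off-carrier bins carry only truncation-level phase sensitivity
  expect_equal(Mod(tf2$coef[, , , interior]), Mod(tf$coef[, , , interior]),
               tolerance = 0.01)

  # direct O(n^2) convolution oracle at interior points
  x <- ep$data[1, 1, ]
  for (f in c(5, 10)) {
    w <- percort:::morlet_wavelet(f, 500)
    half <- (length(w) - 1) / 2
    k <- which(tf$freqs == f)
    for (ti in c(mid, mid + 40)) {
      direct <- sum(x[ti - (-half:half)] * w[half + 1 + (-half:half)])
      expect_equal(tf$coef[1, 1, k, ti], direct, tolerance = 1e-8)
    }
  }
})

test_that("Morlet decomposition validates frequencies and epoch length", {
  ep <- make_sine_epochs(window = c(-1, 1))
  expect_error(morlet_tf(ep, freqs = c(10, 300)), "Nyquist")
  short <- make_sine_epochs(window = c(-0.2, 0.2))
  expect_error(morlet_tf(short, freqs = 1:5), "too short")
})

test_that("cropped/decimated coefficients agree with the full decomposition", {
  ep <- make_sine_epochs(freq = 9, n_trials = 2, window = c(-1, 1), noise_sd = 0.5)
  full <- morlet_tf(ep, freqs = 5:15)
  part <- morlet_tf(ep, freqs = 5:15, crop = c(-0.3, 0.3), decimate = 5)
  sel <- match(round(part$times, 9), round(full$times, 9))
  expect_equal(part$coef[, , , ], full$coef[, , , sel], tolerance = 1e-9)
})

test_that("dB power normalization: doubling amplitude gives +6.02 dB at the carrier", {
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  gain <- ifelse(t >= 0 & t < 0.6, 2, 1)
  d <- array(0, c(2, 1, length(t)))
  for (r in 1:2) d[r, 1, ] <- gain * sin(2 * pi * 10 * t)
  ep <- eeg_epochs(d, t, 500, channel_labels = "c")
  pm <- power_db(morlet_tf(ep, freqs = 5:15))
  k <- which(pm$freqs == 10)
  mid <- which.min(abs(pm$times - 0.3))
  expect_equal(pm$db[1, k, mid], 10 * log10(4), tolerance = 0.05)

  zero <- eeg_epochs(array(0, c(2, 1, length(t))), t, 500, channel_labels = "z")
  expect_error(power_db(morlet_tf(zero, freqs = 5:15)), "zero baseline")
})

test_that("dB maps are invariant to global rescaling of the signal", {
  set.seed(11)
  ep <- make_sine_epochs(freq = 8, n_trials = 4, noise_sd = 1, window = c(-1, 1))
  tf1 <- morlet_tf(ep, freqs = 5:15)
  ep$data <- ep$data * 137
  tf2 <- morlet_tf(ep, freqs = 5:15)
  expect_equal(power_db(tf2)$db, power_db(tf1)$db, tolerance = 1e-9)
})

test_that("stationary noise has near-zero mean response dB at 90 trials", {
  set.seed(12)
  d <- array(rnorm(90 * 1 * 1000), c(90, 1, 1000))
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  ep <- eeg_epochs(d, t, 500, channel_labels = "n")
  pm <- power_db(morlet_tf(ep, freqs = seq(10, 40, 5)))
  resp <- pm$times >= 0 & pm$times < 0.8
  expect_lt(abs(mean(pm$db[1, , resp])), 0.2)
})

test_that("bootstrap power mask controls false positives and finds planted bursts", {
  expect_error(bootstrap_mask_power(make_tf(array(1i, c(3, 1, 2, 10)), 1:2,
                                            seq(-0.5, 0.4, by = 0.1)),
                                    n_perm = 10, alpha = 0.05, seed = 1),
               "n_perm")
  set.seed(13)
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  d <- array(rnorm(60 * 2 * 1000), c(60, 2, 1000))
  ep <- eeg_epochs(d, t, 500, channel_labels = c("a", "b"))
  tf <- morlet_tf(ep, freqs = seq(6, 40, 2))
  pm <- bootstrap_mask_power(tf, n_perm = 500, seed = 21)
  resp <- pm$times >= 0 & pm$times < 0.8
  expect_lte(mean(pm$mask[, , resp]), 0.05 + 0.02)

  # plant a strong 10 Hz burst in 0.1-0.4 s on channel 1
  burst <- ifelse(t >= 0.1 & t < 0.4, 8, 0) * sin(2 * pi * 10 * t)
  for (r in 1:60) d[r, 1, ] <- d[r, 1, ] + burst
  ep2 <- eeg_epochs(d, t, 500, channel_labels = c("a", "b"))
  pm2 <- bootstrap_mask_power(morlet_tf(ep2, freqs = seq(6, 40, 2)),
                              n_perm = 500, seed = 21)
  k <- which(pm2$freqs == 10)
  win <- pm2$times >= 0.15 & pm2$times < 0.35
  expect_true(all(pm2$db[1, k, win] > 0))
  expect_true(all(pm2$mask[1, k, win]))
  # masked entries are exactly zero, unmasked equal the raw values
  expect_true(all(pm2$db[!pm2$mask] == 0))
  expect_equal(pm2$db[pm2$mask], pm2$db_raw[pm2$mask])
})

test_that("band averages equal the brute-force triple loop and handle masks", {
  set.seed(14)
  db <- array(rnorm(3 * 6 * 20), c(3, 6, 20))
  pm <- make_power_map(db, freqs = 5:10, times = seq(0, 0.95, by = 0.05))
  got <- band_average(pm, band = c(6, 8), time_window = c(0.1, 0.5),
                      channels = c(1, 3))
  acc <- c()
  for (ch in c(1, 3)) for (f in which(pm$freqs >= 6 & pm$freqs <= 8))
    for (ti in which(pm$times >= 0.1 & pm$times < 0.5))
      acc <- c(acc, db[ch, f, ti])
  expect_equal(got, mean(acc), tolerance = 1e-12)

  flat <- make_power_map(array(-1, c(2, 3, 5)), 1:3, seq(0, 0.4, 0.1))
  expect_equal(band_average(flat, c(1, 3), c(0, 0.5)), -1)
  zero <- make_power_map(array(0, c(2, 3, 5)), 1:3, seq(0, 0.4, 0.1))
  expect_equal(band_average(zero, c(1, 3), c(0, 0.5)), 0)
  expect_error(band_average(flat, c(1, 3), c(0.41, 0.5)), "no samples")
})

test_that("band definitions cover the analysis bands within 1-40 Hz", {
  b <- band_definitions()
  expect_equal(b$hf, c(20, 40))
  expect_equal(b$theta_alpha, c(5, 14))
  expect_true(all(vapply(b, function(x) x[1] >= 1 && x[2] <= 40, TRUE)))
})
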