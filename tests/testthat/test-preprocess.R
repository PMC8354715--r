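make_session <- function(signal, rate = 500) {
  eeg_session(signal, rate, channel_labels = paste0("ch", seq_len(nrow(signal))))
}

test_that("common-average referencing zeroes the instantaneous channel mean and is idempotent", {
  set.seed(4)
  s <- make_session(matrix(rnorm(4 * 3000, sd = 20), 4))
  c1 <- condition_signal(s, "common_average")
  expect_lt(max(abs(colMeans(c1$signal))), 1e-9 * stats::sd(s$signal))
  # referencing is idempotent: subtracting the channel mean again changes nothing
  again <- sweep(c1$signal, 2, colMeans(c1$signal))
  expect_equal(again, c1$signal, tolerance = 1e-8)
  expect_identical(c1$reference, "common_average")
})

test_that("band-pass passes 10 Hz within 1% and removes DC below the 0.5 Hz edge", {
  t <- (0:9999) / 500
  sine <- 100 * sin(2 * pi * 10 * t)
  s <- make_session(rbind(sine, sine))
  out <- condition_signal(s, "raw")
  mid <- 2000:8000
  expect_lt(abs(max(abs(out$signal[1, mid])) / 100 - 1), 0.01)

  dc <- make_session(matrix(100, 2, 10000))
  out2 <- condition_signal(dc, "raw")
  expect_lt(abs(mean(out2$signal[1, 2000:8000])), 1)
  # the designed zero-phase filter truly annihilates 0 Hz
  bf <- signal::butter(3, c(0.5, 80) / 250, type = "pass")
  expect_lt(abs(sum(bf$b) / sum(bf$a))^2, 1e-6)
})

test_that("polyphase resampling halves the grid and preserves passband amplitude", {
  t <- (0:19999) / 1000
  s <- make_session(rbind(50 * sin(2 * pi * 10 * t), 50 * cos(2 * pi * 10 * t)),
                    rate = 1000)
  out <- condition_signal(s, "raw", target_rate = 500)
  expect_equal(out$rate, 500)
  expect_equal(ncol(out$signal), 10000)
  # interior rms preserved up to the resampler's small passband droop
  expect_lt(abs(percort:::rms(out$signal[1, 2000:8000]) / (50 / sqrt(2)) - 1), 0.05)
})

test_that("bipolar referencing derives one labeled difference channel and validates names", {
  set.seed(5)
  s <- make_session(matrix(rnorm(3 * 2000), 3))
  out <- condition_signal(s, "bipolar", pair = c("ch1", "ch3"), band = c(0.5, 80))
  expect_equal(nrow(out$signal), 1)
  expect_identical(out$channel_labels, "ch1-ch3")
  expect_error(condition_signal(s, "bipolar", pair = c("ch1", "nope")), "absent")
  expect_error(condition_signal(s, "raw", target_rate = 1000), "exceeds")
})

test_that("epoching yields 5000-sample epochs with exactly zero baseline mean", {
  set.seed(6)
  sig <- matrix(rnorm(2 * 20000, mean = 7), 2)
  s <- eeg_session(sig, 500, channel_labels = c("a", "b"),
                   events = data.frame(onset_s = c(6, 16, 26),
                                       intensity_uA = c(50, 50, 50)))
  ep <- epoch_and_correct(s)
  expect_equal(dim(ep$data), c(3, 2, 5000))
  expect_equal(diff(range(ep$time_axis)), 10 - 1 / 500)
  expect_true(any(abs(ep$time_axis) < 1e-12))
  bidx <- which(ep$time_axis >= -1 & ep$time_axis < 0)
  bm <- apply(ep$data[, , bidx], c(1, 2), mean)
  expect_lt(max(abs(bm)), 1e-9)
})

test_that("events too close to the recording edge are reported and skipped", {
  s <- eeg_session(matrix(rnorm(2 * 3000), 2), 500,
                   channel_labels = c("a", "b"),
                   events = data.frame(onset_s = 2, intensity_uA = 50))
  expect_error(expect_message(epoch_and_correct(s), "skipping"), "no event")
  s2 <- eeg_session(matrix(rnorm(2 * 13000), 2), 500,
                    channel_labels = c("a", "b"),
                    events = data.frame(onset_s = c(2, 13), intensity_uA = c(50, 50)))
  expect_message(ep <- epoch_and_correct(s2), "2 s")
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(ep$provenance$skipped_events, 1L)
})

test_that("stimulus-artifact interpolation touches only the window and reproduces smooth signals", {
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  cubic <- 2 + 3 * t - 4 * t^2 + 5 * t^3          # splines restore cubics exactly
  d <- array(rep(cubic, each = 2), dim = c(2, 1, length(t)))
  d <- aperm(d, c(1, 2, 3))
  for (r in 1:2) d[r, 1, ] <- cubic
  spike <- which.min(abs(t - 0.002))
  d[, 1, spike] <- 2000
  ep <- eeg_epochs(d, t, 500, channel_labels = "ch1")
  out <- interpolate_stim_artifact(ep)
  win <- which(t >= 0 & t <= 0.005)
  expect_lt(max(abs(out$data[1, 1, win] - cubic[win])), 1e-8)
  outside <- setdiff(seq_along(t), win)
  expect_identical(out$data[, , outside], ep$data[, , outside])
  i6 <- which.min(abs(t - 0.006))
  expect_identical(out$data[1, 1, i6], ep$data[1, 1, i6])

  zero <- eeg_epochs(array(0, c(1, 1, length(t))), t, 500, channel_labels = "z")
  expect_equal(interpolate_stim_artifact(zero)$data, zero$data)
  expect_error(interpolate_stim_artifact(ep, window = c(0, 10)), "exceeds")
})

test_that("trial rejection applies the mean + 3 SD pooled-baseline-rms rule", {
  t <- seq(-1.2, 0.5 - 1 / 500, by = 1 / 500)
  nt <- length(t)
  # identical trials: SD = 0, strict comparison keeps everything
  same <- eeg_epochs(array(5, c(4, 2, nt)), t, 500,
                     channel_labels = c("a", "b"))
  expect_length(reject_trials(same)$report$rejected, 0)

  # one wild trial among 90 calm ones
  set.seed(7)
  d <- array(rnorm(90 * 2 * nt, sd = 10), c(90, 2, nt))
  d[37, , ] <- rnorm(2 * nt, sd = 200)
  ep <- eeg_epochs(d, t, 500, channel_labels = c("a", "b"))
  res <- reject_trials(ep)
  expect_equal(res$report$rejected, 37L)
  expect_false(res$epochs$kept_mask[37])
  expect_equal(sum(res$epochs$kept_mask), 89)

  # oracle: direct enumeration of the rule
  bidx <- which(t >= -1 & t < 0)
  rms_direct <- sapply(1:90, function(r) sqrt(mean(d[r, , bidx]^2)))
  thr <- mean(rms_direct) + 3 * sd(rms_direct)
  expect_equal(res$report$threshold, thr)
  expect_equal(res$report$rejected, which(rms_direct > thr))

  expect_error(reject_trials(eeg_epochs(array(0, c(1, 2, nt)), t, 500,
                                        channel_labels = c("a", "b"))),
               "at least 2")
})
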