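pair_tf <- function(phase_list, n_time = 12) {
  # phase_list: per-channel vector of trial phases (constant over freq/time)
  n <- length(phase_list[[1]])
  nch <- length(phase_list)
  coef <- array(0i, c(n, nch, 2, n_time))
  for (c in seq_len(nch)) for (r in seq_len(n))
    coef[r, c, , ] <- exp(1i * phase_list[[c]][r])
  make_tf(coef, freqs = c(8, 12), times = seq(-0.5, by = 0.1, length.out = n_time))
}

test_that("ISPC attains closed-form values and equals the brute-force trial mean", {
  set.seed(50)
  ph1 <- runif(30, 0, 2 * pi)
  same_diff <- pair_tf(list(ph1, ph1 - 1.1))       # constant lag 1.1 rad
  expect_equal(max(abs(ispc_map(same_diff)$ispc - 1)), 0, tolerance = 1e-12)

  uni <- pair_tf(list(2 * pi * (0:29) / 30, rep(0, 30)))
  expect_lt(max(ispc_map(uni)$ispc), 1e-12)

  rnd <- pair_tf(list(runif(30, 0, 2 * pi), runif(30, 0, 2 * pi),
                      runif(30, 0, 2 * pi)))
  im <- ispc_map(rnd)
  for (p in seq_len(nrow(im$pairs))) {
    x <- im$pairs[p, 1]; y <- im$pairs[p, 2]
    acc <- 0i
    for (r in 1:30)
      acc <- acc + exp(1i * (Arg(rnd$coef[r, x, 1, 1]) - Arg(rnd$coef[r, y, 1, 1])))
    expect_equal(im$ispc[p, 1, 1], Mod(acc / 30), tolerance = 1e-12)
  }
  expect_error(ispc_map(pair_tf(list(runif(1), runif(1)))), "2 trials")
})

test_that("volume-conduction v test excludes zero-lag and sign-flipped duplicates", {
  set.seed(51)
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  base <- matrix(rnorm(40 * 1000), 40)
  d <- array(0, c(40, 3, 1000))
  for (r in 1:40) {
    d[r, 1, ] <- base[r, ] + rnorm(1000, sd = 0.01)
    d[r, 2, ] <- base[r, ] + rnorm(1000, sd = 0.01)   # near-duplicate: 0 lag
    d[r, 3, ] <- -base[r, ] + rnorm(1000, sd = 0.01)  # sign flip: pi lag
  }
  ep <- eeg_epochs(d, t, 500, channel_labels = c("a", "b", "c"))
  tf <- morlet_tf(ep, freqs = c(8, 10, 12), crop = c(-0.6, 0.5), decimate = 5)
  isp <- ispc_significant(ispc_map(tf), seed = 61,
                          windows = list(c(0.08, 0.18)))
  p_ab <- which(isp$pairs[, 1] == 1 & isp$pairs[, 2] == 2)
  p_ac <- which(isp$pairs[, 1] == 1 & isp$pairs[, 2] == 3)
  expect_true(all(isp$excluded[p_ab, , 1]))
  expect_true(all(isp$excluded[p_ac, , 1]))
})

test_that("independent noise channels rarely count as connected", {
  set.seed(52)
  t <- seq(-1, 1 - 1 / 500, by = 1 / 500)
  d <- array(rnorm(60 * 4 * 1000), c(60, 4, 1000))
  ep <- eeg_epochs(d, t, 500, channel_labels = paste0("ch", 1:4))
  tf <- morlet_tf(ep, freqs = c(6, 9, 12), crop = c(-0.6, 0.5), decimate = 5)
  isp <- ispc_significant(ispc_map(tf), seed = 62,
                          windows = list(c(0.08, 0.18)))
  resp <- isp$times >= 0 & isp$times < 0.5
  expect_lte(mean(isp$mask[, , resp]), 0.05 + 0.02)
})

test_that("connectivity degree counts partners, normalizes by channels - 1, and is symmetric", {
  nch <- 6
  pairs <- t(combn(nch, 2))
  times <- seq(-0.5, 0.49, by = 0.01)
  freqs <- 5:14
  mk <- function(connected_pairs) {
    corr <- array(0, c(nrow(pairs), length(freqs), length(times)))
    corr[connected_pairs, , ] <- 0.3
    structure(list(ispc = corr, corrected = corr, mask = corr > 0,
                   excluded = array(FALSE, c(nrow(pairs), length(freqs), 1)),
                   exclusion_windows = list(c(0.18, 0.30)),
                   pairs = pairs, freqs = freqs, times = times, n_trials = 30,
                   channel_labels = paste0("ch", seq_len(nch)),
                   boot = list()), class = "ispc_map")
  }
  all_cd <- connectivity_degree(mk(seq_len(nrow(pairs))), window = c(0.18, 0.30))
  expect_equal(unname(all_cd$cd), rep(1, nch))
  none_cd <- connectivity_degree(mk(integer(0)), window = c(0.18, 0.30))
  expect_equal(unname(none_cd$cd), rep(0, nch))

  # ch1 connected to exactly 3 of its 5 partners
  sel <- which(pairs[, 1] == 1)[1:3]
  cd3 <- connectivity_degree(mk(sel), window = c(0.18, 0.30))
  expect_equal(unname(cd3$cd[1]), 3 / 5)
  expect_true(isSymmetric(cd3$matrix))
  # each connected pair contributes to both endpoints
  expect_equal(sum(cd3$matrix) / 2, 3)

  # excluding one pair never increases any channel's degree
  m <- mk(seq_len(nrow(pairs)))
  m$excluded[5, , 1] <- TRUE
  cd_excl <- connectivity_degree(m, window = c(0.18, 0.30))
  expect_true(all(cd_excl$cd <= all_cd$cd))
  expect_error(connectivity_degree(m, window = c(0, 0.1)), "exclusion windows")
})

test_that("regional degree means follow the standard montage partition", {
  mont <- rat_montage()
  expect_equal(sum(mont$region == "frontal"), 6)
  expect_equal(sum(mont$region == "parietal"), 6)
  expect_equal(sum(mont$region == "occipital"), 4)
  pairs <- t(combn(16, 2))
  corr <- array(0, c(nrow(pairs), 2, 5))
  occ <- which(mont$region == "occipital")
  sel <- which(pairs[, 1] %in% occ & pairs[, 2] %in% occ)
  corr[sel, , ] <- 1
  m <- structure(list(ispc = corr, corrected = corr, mask = corr > 0,
                      excluded = array(FALSE, c(nrow(pairs), 2, 1)),
                      exclusion_windows = list(c(0.18, 0.30)),
                      pairs = pairs, freqs = c(8, 10),
                      times = seq(0.18, 0.26, by = 0.02), n_trials = 30,
                      channel_labels = mont$label, boot = list()),
                 class = "ispc_map")
  cd <- connectivity_degree(m, window = c(0.18, 0.30))
  expect_gt(cd$regional["occipital"], cd$regional["frontal"])
  expect_gt(cd$regional["occipital"], cd$regional["parietal"])
  expect_equal(unname(cd$regional["occipital"]), 3 / 15)
})

test_that("connectivity matrices export as square labeled text", {
  pairs <- t(combn(3, 2))
  corr <- array(0.2, c(3, 1, 2))
  m <- structure(list(ispc = corr, corrected = corr, mask = corr > 0,
                      excluded = array(FALSE, c(3, 1, 1)),
                      exclusion_windows = list(c(0.18, 0.30)),
                      pairs = pairs, freqs = 10, times = c(0.2, 0.25),
                      n_trials = 10, channel_labels = c("a", "b", "c"),
                      boot = list()), class = "ispc_map")
  cd <- connectivity_degree(m, band = c(5, 14), window = c(0.18, 0.30))
  p <- tempfile()
  write_connectivity_matrix(cd, p)
  back <- as.matrix(read.table(p, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(back), unname(cd$matrix))
  unlink(p)
})
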