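# Fixture builders shared across the test files. Everything is generated in
# code at test time; no stored data.

# Epochs holding per-trial sinusoids: `phases` gives one phase offset per
# trial (recycled across channels unless `channel_phase` adds per-channel
# offsets). Optional white noise.
make_sine_epochs <- function(freq = 10, n_trials = 8, n_channels = 2,
                             amp = 1, phases = rep(0, n_trials),
                             channel_phase = rep(0, n_channels),
                             window = c(-1, 1), rate = 500, noise_sd = 0,
                             seed = 1) {
  nt <- round(diff(window) * rate)
  t <- window[1] + (seq_len(nt) - 1) / rate
  set.seed(seed)
  d <- array(0, dim = c(n_trials, n_channels, nt))
  for (r in seq_len(n_trials)) for (c in seq_len(n_channels))
    d[r, c, ] <- amp * sin(2 * pi * freq * t + phases[r] + channel_phase[c]) +
      if (noise_sd > 0) rnorm(nt, 0, noise_sd) else 0
  eeg_epochs(d, t, rate, channel_labels = paste0("ch", seq_len(n_channels)))
}

# tf_decomp with prescribed coefficients (for closed-form ITPC/ISPC checks).
make_tf <- function(coef, freqs, times, rate = 100) {
  structure(list(coef = coef, freqs = freqs, times = times, rate = rate,
                 cycles = 3,
                 channel_labels = paste0("ch", seq_len(dim(coef)[2])),
                 channel_xy = matrix(0, dim(coef)[2], 2)),
            class = "tf_decomp")
}

# Unmasked-free power_map with prescribed dB values and full mask (for the
# OFF-period / late-HF / LF feature unit tests).
make_power_map <- function(db, freqs, times, labels = NULL) {
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(db)[1]))
  structure(list(db = db, mask = db != 0, freqs = freqs, times = times,
                 baseline = matrix(1, dim(db)[1], dim(db)[2]),
                 baseline_window = c(-0.5, -0.2),
                 channel_labels = labels,
                 channel_xy = matrix(0, dim(db)[1], 2),
                 boot = list(alpha = 0.05, n_perm = 500)),
            class = "power_map")
}

# Minimal continuous-record EDF writer used as the independent counterpart of
# read_edf(): header fields per the published 256-byte layout, 16-bit LE
# samples, one data record per second.
write_edf_fixture <- function(path, signal, rate, labels = NULL,
                              phys_range = c(-500, 500)) {
  nch <- nrow(signal)
  if (is.null(labels)) labels <- paste0("sig", seq_len(nch))
  n_rec <- ncol(signal) / rate
  stopifnot(n_rec == round(n_rec))
  dmin <- -32768; dmax <- 32767
  pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad(x, n)), con)
  wr("0", 8); wr("test subject", 80); wr("test recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 + 256 * nch, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(nch, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(phys_range[1], 8)
  for (i in seq_len(nch)) wr(phys_range[2], 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(rate, 8)
  for (i in seq_len(nch)) wr("", 32)
  scale <- (dmax - dmin) / diff(phys_range)
  dig <- round((signal - phys_range[1]) * scale + dmin)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * rate + seq_len(rate)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}
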