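#' Frequency bands used throughout the analysis
#'
#' delta 1-4, theta 5-7, alpha 8-14, beta 15-25, gamma 26-40, HF 20-40,
#' LF 1-4, broad 8-40, theta-alpha 5-14 Hz. Band edges are inclusive.
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
band_definitions <- function() {
  list(delta = c(1, 4), theta = c(5, 7), alpha = c(8, 14), beta = c(15, 25),
       gamma = c(26, 40), hf = c(20, 40), lf = c(1, 4), broad = c(8, 40),
       theta_alpha = c(5, 14))
}

#' Trial-averaged FFT periodogram of spontaneous activity
#'
#' Per kept epoch, the FFT of the selected window is normalized by the sample
#' count N and its squared modulus averaged over trials. Stored two-sided
#' (`power_full`), reported one-sided (`power` at `frequencies`, without
#' doubling, so a sinusoid of amplitude A peaks at A^2/4).
#'
#' @param epochs an [eeg_epochs()].
#' @param window analysis window in seconds (default -5 to -1, the 4 s
#'   pre-stimulus baseline).
#' @param channels one channel label/index (that channel), or two (their
#'   difference, a bipolar derivation, the convention for spontaneous activity).
#' @return Object of class `eeg_spectrum`: `frequencies`, `power` (one-sided),
#'   `power_full`, `frequencies_full`, `n_epochs`, `n_samples`.
#' @export
periodogram_mean <- function(epochs, window = c(-5, -1), channels = 1) {
  x <- kept_data(epochs)
  if (dim(x)[1] == 0) stop("no kept trials")
  idx <- time_indices(epochs$time_axis, window)
  ch <- channels
  if (is.character(ch)) ch <- match(ch, epochs$channel_labels)
  if (anyNA(ch)) stop("unknown channel label")
  n <- length(idx)
  acc <- numeric(n)
  for (r in seq_len(dim(x)[1])) {
    ts <- if (length(ch) == 2) x[r, ch[1], idx] - x[r, ch[2], idx] else x[r, ch[1], idx]
    acc <- acc + Mod(fft(ts) / n)^2
  }
  pw <- acc / dim(x)[1]
  freqs_full <- (seq_len(n) - 1) * epochs$rate / n
  half <- seq_len(floor(n / 2) + 1)
  structure(list(frequencies = freqs_full[half], power = pw[half],
                 power_full = pw, frequencies_full = freqs_full,
                 n_epochs = dim(x)[1], n_samples = n, rate = epochs$rate),
            class = "eeg_spectrum")
}

#' Spectral exponent (log-log slope) of a periodogram
#'
#' Least-squares slope of log10(power) against log10(frequency) within the
#' band, the standard aperiodic 1/f exponent. More negative slopes indicate
#' redistribution of power toward low frequencies.
#'
#' @param spectrum an `eeg_spectrum` from [periodogram_mean()].
#' @param band fit range in Hz (default 20-40).
#' @return Scalar slope (dimensionless).
#' @export
spectral_exponent <- function(spectrum, band = c(20, 40)) {
  idx <- band_indices(spectrum$frequencies, band)
  idx <- idx[spectrum$frequencies[idx] > 0]
  if (length(idx) < 3) stop("band must cover at least 3 frequency bins")
  p <- spectrum$power[idx]
  if (any(p <= 0)) stop("nonpositive power in the fitted band")
  unname(coef(lm(log10(p) ~ log10(spectrum$frequencies[idx])))[2])
}

# Complex Morlet wavelet at frequency f: Gaussian envelope with
# sigma_t = cycles/(2*pi*f), truncated at +-4 SD, normalized so that a
# sinusoid of amplitude A yields |coefficient| ~ A.
morlet_wavelet <- function(f, rate, cycles = 3) {
  sigma <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma * rate)
  tw <- (-half:half) / rate
  env <- exp(-tw^2 / (2 * sigma^2))
  w <- env * exp(2i * pi * f * tw)
  w * (2 / sum(env))
}

#' Morlet wavelet decomposition of epochs
#'
#' Complex convolution of every kept trial and channel with a family of Morlet
#' wavelets (default: 40 wavelets, 3 cycles, linearly spanning 1-40 Hz),
#' computed on the full epoch so edge effects stay outside the analysis
#' windows. The retained coefficients can be cropped in time and decimated to
#' keep memory bounded; phases and powers are unaffected by either.
#'
#' @param epochs an [eeg_epochs()].
#' @param freqs wavelet center frequencies in Hz (default 1:40).
#' @param cycles wavelet cycles (default 3).
#' @param crop optional `c(t0, t1)` window of coefficients to retain (seconds).
#' @param decimate integer step for the retained time grid (default 1 = full
#'   rate).
#' @return Object of class `tf_decomp`: complex array `coef` (trials x channels
#'   x frequencies x time), `freqs`, `times`, `rate` (of the retained grid),
#'   `channel_labels`, `channel_xy`, `cycles`.
#' @export
morlet_tf <- function(epochs, freqs = 1:40, cycles = 3, crop = NULL, decimate = 1L) {
  x <- kept_data(epochs)
  nt <- dim(x)[3]; nch <- dim(x)[2]; ntr <- dim(x)[1]
  if (ntr == 0) stop("no kept trials")
  if (max(freqs) > epochs$rate / 2)
    stop("frequency ", max(freqs), " Hz exceeds the Nyquist rate")
  wl <- lapply(freqs, morlet_wavelet, rate = epochs$rate, cycles = cycles)
  nw <- max(vapply(wl, length, 0L))
  if (nt < nw)
    stop("epoch too short for the longest wavelet (", nw, " samples at ",
         min(freqs), " Hz)")
  tsel <- seq_len(nt)
  if (!is.null(crop)) tsel <- time_indices(epochs$time_axis, crop)
  tsel <- tsel[seq(1, length(tsel), by = decimate)]
  times <- epochs$time_axis[tsel]
  # circular convolution suffices when the retained samples sit further from
  # the epoch edges than the longest wavelet half-support
  halfmax <- (nw - 1) / 2
  circ_ok <- min(tsel) > halfmax && max(tsel) + halfmax <= nt
  L <- if (circ_ok) nt else stats::nextn(nt + nw - 1, 2)
  wf <- vapply(wl, function(w) {
    half <- (length(w) - 1) / 2
    fft(c(w, rep(0 + 0i, L - length(w))))
  }, complex(L))
  coef <- array(0i, dim = c(ntr, nch, length(freqs), length(tsel)))
  delays <- vapply(wl, function(w) (length(w) - 1) / 2, 0)
  for (c in seq_len(nch)) {
    xc <- matrix(x[, c, , drop = FALSE], ntr, nt)  # trials x time
    X <- mvfft(rbind(t(xc), matrix(0, L - nt, ntr)))
    for (k in seq_along(freqs)) {
      Cf <- mvfft(X * wf[, k], inverse = TRUE) / L
      coef[, c, k, ] <- t(Cf[tsel + delays[k], , drop = FALSE])
    }
  }
  structure(list(coef = coef, freqs = freqs, times = times,
                 rate = epochs$rate / decimate, cycles = cycles,
                 channel_labels = epochs$channel_labels,
                 channel_xy = epochs$channel_xy),
            class = "tf_decomp")
}

#' @export
print.tf_decomp <- function(x, ...) {
  d <- dim(x$coef)
  cat("<tf_decomp> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " freqs x ", d[4], " samples (", sprintf("%.2f..%.2f", min(x$times),
      max(x$times)), " s @ ", x$rate, " Hz)\n", sep = "")
  invisible(x)
}

#' Baseline-normalized spectral power in decibels
#'
#' Per trial, channel and frequency the squared coefficient magnitude is
#' normalized by the trial-averaged baseline power of that channel/frequency,
#' averaged over trials, and converted to dB (10*log10).
#'
#' @param tf a [morlet_tf()] decomposition.
#' @param baseline baseline window in seconds (default -0.5 to -0.2).
#' @return Object of class `power_map`: `db` (channels x frequencies x time),
#'   `mask = NULL` (unmasked), `freqs`, `times`, `baseline`.
#' @export
power_db <- function(tf, baseline = c(-0.5, -0.2)) {
  bidx <- time_indices(tf$times, baseline)
  P <- Mod(tf$coef)^2
  bm <- colMeans(P[, , , bidx, drop = FALSE])        # channels x freqs x nb
  base <- rowMeans(matrix(bm, prod(dim(bm)[1:2])))
  base <- matrix(base, dim(bm)[1], dim(bm)[2])       # channels x freqs
  if (any(base <= 0)) stop("zero baseline power; cannot normalize")
  mp <- colMeans(P)
  db <- 10 * log10(sweep(mp, c(1, 2), base, "/"))
  structure(list(db = db, mask = NULL, freqs = tf$freqs, times = tf$times,
                 baseline = base, baseline_window = baseline,
                 channel_labels = tf$channel_labels,
                 channel_xy = tf$channel_xy, boot = NULL),
            class = "power_map")
}

# Shared index matrix for the baseline-resampling null: one baseline time point
# per trial and draw, K draws per permutation (K = number of baseline samples,
# so each permutation emulates a full surrogate baseline series whose extremes
# are taken).
null_draw_idx <- function(nb, ntr, n_perm, seed) {
  with_seed(seed, matrix(sample.int(nb, ntr * nb * n_perm, replace = TRUE), ntr))
}

#' Bootstrap significance mask for a dB power map
#'
#' Builds the null by resampling baseline time points: per permutation, one
#' baseline time point is drawn per trial for each of K = (baseline samples)
#' draws, the trial-averaged dB statistic is recomputed for each draw, and the
#' permutation's extremes are kept. The positive and negative thresholds are
#' the `1 - alpha/2` and `alpha/2` percentiles of those extremes per channel
#' and frequency: a value is significant only when it exceeds what the
#' unperturbed baseline process produces anywhere along a surrogate baseline.
#' Non-significant dB values are set to exactly 0.
#'
#' @param tf a [morlet_tf()] decomposition.
#' @param baseline baseline window (default -0.5 to -0.2 s).
#' @param n_perm permutations (default 500).
#' @param alpha two-sided level (default 0.05).
#' @param seed RNG seed (required; logged in the result).
#' @return A masked `power_map`: `db` thresholded (non-significant entries 0),
#'   `db_raw` unmasked, `mask` logical, `boot` parameters.
#' @export
bootstrap_mask_power <- function(tf, baseline = c(-0.5, -0.2), n_perm = 500,
                                 alpha = 0.05, seed) {
  if (n_perm < 1 / alpha) stop("n_perm too small to resolve alpha = ", alpha)
  pm <- power_db(tf, baseline)
  bidx <- time_indices(tf$times, baseline)
  P <- Mod(tf$coef)^2
  d <- dim(P)  # trials, channels, freqs, time
  ntr <- d[1]; ncf <- d[2] * d[3]; nb <- length(bidx)
  Pb <- P[, , , bidx, drop = FALSE]
  dim(Pb) <- c(ntr, ncf, nb)
  Pb <- aperm(Pb, c(1, 3, 2))   # (trials, baseline samples, cells)
  idx <- null_draw_idx(nb, ntr, n_perm, seed)
  ext <- perm_null_minmax_real(Pb, c(ntr, nb, ncf), idx, n_perm, nb)
  base <- as.numeric(pm$baseline)
  hi <- apply(10 * log10(sweep(ext$max, 2, base, "/")), 2, quantile,
              probs = 1 - alpha / 2, names = FALSE)
  lo <- apply(10 * log10(sweep(ext$min, 2, base, "/")), 2, quantile,
              probs = alpha / 2, names = FALSE)
  lo_a <- array(lo, dim = d[2:3]); hi_a <- array(hi, dim = d[2:3])
  mask <- sweep(pm$db, c(1, 2), hi_a, ">") | sweep(pm$db, c(1, 2), lo_a, "<")
  pm$db_raw <- pm$db
  pm$db <- pm$db * mask
  pm$mask <- mask
  pm$boot <- list(n_perm = n_perm, alpha = alpha, seed = seed,
                  baseline_window = baseline, thresholds = list(lo = lo_a, hi = hi_a))
  pm
}

#' @export
print.power_map <- function(x, ...) {
  d <- dim(x$db)
  cat("<power_map> ", d[1], " channels x ", d[2], " freqs x ", d[3], " samples; ",
      if (is.null(x$mask)) "unmasked" else
        sprintf("masked (alpha = %g, %d perms)", x$boot$alpha, x$boot$n_perm),
      "\n", sep = "")
  invisible(x)
}

#' Average a (masked) power map over a band, window and channel set
#'
#' @param powermap a `power_map`.
#' @param band frequency band `c(lo, hi)` in Hz, edges inclusive.
#' @param time_window `c(t0, t1)` in seconds, closed-left open-right.
#' @param channels channel indices or labels (default: all).
#' @return Scalar mean dB.
#' @export
band_average <- function(powermap, band, time_window, channels = NULL) {
  fidx <- band_indices(powermap$freqs, band)
  tidx <- time_indices(powermap$times, time_window)
  ch <- channels
  if (is.null(ch)) ch <- seq_len(dim(powermap$db)[1])
  if (is.character(ch)) ch <- match(ch, powermap$channel_labels)
  if (anyNA(ch) || length(ch) == 0) stop("empty or unknown channel selection")
  mean(powermap$db[ch, fidx, tidx])
}
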