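# Unit phasors of the decomposition; zero-magnitude coefficients (which carry
# no phase) are treated as zero phasors so they dilute rather than corrupt.
unit_phasors <- function(tf) {
  m <- Mod(tf$coef)
  u <- tf$coef
  nz <- m > 0
  u[nz] <- u[nz] / m[nz]
  u[!nz] <- 0 + 0i
  u
}

#' Intertrial phase clustering (ITPC)
#'
#' ITPC at each channel, frequency and time point is the modulus of the mean
#' unit phasor over trials: 1 when all trials share the phase, 0 when the
#' phases cancel (e.g. uniformly spaced around the circle).
#'
#' @param tf a [morlet_tf()] decomposition with at least 2 trials.
#' @return Object of class `itpc_map`: `itpc` (channels x frequencies x time in
#'   `[0, 1]`), `mask = NULL`, `freqs`, `times`.
#' @export
itpc_map <- function(tf) {
  ntr <- dim(tf$coef)[1]
  if (ntr < 2) stop("ITPC needs at least 2 trials")
  u <- unit_phasors(tf)
  itpc <- Mod(colMeans(u))
  structure(list(itpc = itpc, mask = NULL, freqs = tf$freqs, times = tf$times,
                 n_trials = ntr, channel_labels = tf$channel_labels,
                 boot = NULL), class = "itpc_map")
}

#' @export
print.itpc_map <- function(x, ...) {
  d <- dim(x$itpc)
  cat("<itpc_map> ", d[1], " channels x ", d[2], " freqs x ", d[3],
      " samples (", x$n_trials, " trials); ",
      if (is.null(x$mask)) "unmasked" else
        sprintf("masked (alpha = %g)", x$boot$alpha), "\n", sep = "")
  invisible(x)
}

#' Bootstrap significance mask for ITPC
#'
#' One-sided null per channel and frequency: per permutation, one baseline
#' time point is drawn per trial for each of K = (baseline samples) draws, the
#' ITPC recomputed for each draw, and the permutation's maximum kept; the
#' (1 - alpha) percentile of those maxima is the threshold, so only ITPC
#' increments exceeding anything the baseline process produces are retained
#' (others set to 0).
#'
#' @param itpcmap an [itpc_map()].
#' @param tf the decomposition the map came from.
#' @param baseline baseline window (default -0.5 to -0.2 s).
#' @param n_perm permutations (default 500).
#' @param alpha one-sided level (default 0.01).
#' @param seed RNG seed.
#' @return The `itpc_map` masked: `itpc` thresholded, `itpc_raw`, `mask`,
#'   `boot` parameters.
#' @export
itpc_mask <- function(itpcmap, tf, baseline = c(-0.5, -0.2), n_perm = 500,
                      alpha = 0.01, seed) {
  if (n_perm < 1 / alpha) stop("n_perm too small to resolve alpha = ", alpha)
  bidx <- time_indices(tf$times, baseline)
  u <- unit_phasors(tf)
  d <- dim(u)
  ntr <- d[1]; ncf <- d[2] * d[3]; nb <- length(bidx)
  Ub <- u[, , , bidx, drop = FALSE]
  dim(Ub) <- c(ntr, ncf, nb)
  Ub <- aperm(Ub, c(1, 3, 2))
  idx <- null_draw_idx(nb, ntr, n_perm, seed)
  ext <- perm_null_minmax_mod(Ub, c(ntr, nb, ncf), idx, n_perm, nb)
  thr <- array(apply(ext$max, 2, quantile, probs = 1 - alpha, names = FALSE),
               dim = d[2:3])
  mask <- sweep(itpcmap$itpc, c(1, 2), thr, ">")
  itpcmap$itpc_raw <- itpcmap$itpc
  itpcmap$itpc <- itpcmap$itpc * mask
  itpcmap$mask <- mask
  itpcmap$boot <- list(n_perm = n_perm, alpha = alpha, seed = seed,
                       baseline_window = baseline, thresholds = thr)
  itpcmap
}

#' ITPC drop time and LF ITPC latency
#'
#' Per channel: the band-mean (default 8-40 Hz) of the masked ITPC is formed
#' and the drop time is the time of the last nonzero value within the window
#' (default 0-0.8 s); 0 with a flag when nothing is significant, and flagged
#' censored when significance persists through the window end. The LF ITPC max
#' latency is taken from the unmasked LF-band (default 1-4 Hz) mean.
#'
#' @param masked_itpc a masked [itpc_map()].
#' @param band broad band for the drop (Hz).
#' @param window search window (s).
#' @param lf_band LF band (Hz).
#' @return Object of class `drop_times`: per-channel `drop_s`, `censored`,
#'   `none_significant`, `lf_max_latency_s`, and channel means.
#' @export
drop_times <- function(masked_itpc, band = c(8, 40), window = c(0, 0.8),
                       lf_band = c(1, 4)) {
  if (is.null(masked_itpc$mask)) stop("drop_times needs a masked ITPC map")
  fidx <- band_indices(masked_itpc$freqs, band)
  lidx <- band_indices(masked_itpc$freqs, lf_band)
  widx <- time_indices(masked_itpc$times, window)
  tt <- masked_itpc$times[widx]
  nch <- dim(masked_itpc$itpc)[1]
  drop_s <- numeric(nch); censored <- logical(nch); none <- logical(nch)
  lf_lat <- numeric(nch)
  raw <- if (is.null(masked_itpc$itpc_raw)) masked_itpc$itpc else masked_itpc$itpc_raw
  for (ch in seq_len(nch)) {
    bm <- colMeans(matrix(masked_itpc$itpc[ch, fidx, widx], length(fidx)))
    nz <- which(bm > 0)
    if (length(nz) == 0) { drop_s[ch] <- 0; none[ch] <- TRUE }
    else {
      drop_s[ch] <- tt[max(nz)]
      censored[ch] <- max(nz) == length(tt)
    }
    lfm <- colMeans(matrix(raw[ch, lidx, widx], length(lidx)))
    lf_lat[ch] <- tt[which.max(lfm)]
  }
  structure(list(drop_s = stats::setNames(drop_s, masked_itpc$channel_labels),
                 censored = censored, none_significant = none,
                 lf_max_latency_s = stats::setNames(lf_lat, masked_itpc$channel_labels),
                 drop_mean = mean(drop_s), lf_max_latency_mean = mean(lf_lat),
                 band = band, window = window), class = "drop_times")
}

#' @export
print.drop_times <- function(x, ...) {
  cat("<drop_times> band ", x$band[1], "-", x$band[2], " Hz: mean drop ",
      sprintf("%.3f", x$drop_mean), " s (", sum(x$censored), " censored, ",
      sum(x$none_significant), " without significance)\n", sep = "")
  invisible(x)
}
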