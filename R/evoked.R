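#' RMS amplitude of the early ERP deflection
#'
#' rms of the trial-averaged ERP within the early-response window
#' (default 0.006-0.05 s), per channel, plus the channel mean.
#'
#' @param epochs an [eeg_epochs()].
#' @param window early-response window in seconds.
#' @return list with `per_channel` (named numeric, microvolts) and `mean`.
#' @export
early_erp_rms <- function(epochs, window = c(0.006, 0.05)) {
  erp <- erp_mean(epochs)
  idx <- time_indices(epochs$time_axis, window)
  per <- apply(erp[, idx, drop = FALSE], 1, rms)
  list(per_channel = per, mean = mean(per))
}

#' Slow component (< 4 Hz) of the evoked response
#'
#' Low-passes every trial (zero-phase Butterworth, 3rd order, default < 4 Hz),
#' quantifies the spontaneous slow-component rms (default -2-0 s) and the
#' evoked rms (default 0-0.3 s) per trial and channel (averaged over both), and
#' locates the maximal absolute peak of the ensemble average (SC max) per
#' channel within 0-0.6 s.
#'
#' @param epochs an [eeg_epochs()] covering at least -2 to 0.6 s.
#' @param cutoff low-pass edge in Hz.
#' @param spont_window,evoked_window rms windows in seconds.
#' @param max_window search window for SC max.
#' @return Object of class `slow_component`: `sp_rms`, `ev_rms` (scalars,
#'   microvolts), `sc_max_amp` and `sc_max_latency` (per channel), plus their
#'   channel means.
#' @export
slow_component <- function(epochs, cutoff = 4, spont_window = c(-2, 0),
                           evoked_window = c(0, 0.3), max_window = c(0, 0.6)) {
  t <- epochs$time_axis
  if (t[1] > spont_window[1] + 1e-9 || t[length(t)] < max_window[2] - 1e-9)
    stop("epochs must cover ", spont_window[1], " to ", max_window[2], " s")
  x <- kept_data(epochs)
  d <- dim(x)
  bf <- signal::butter(3, cutoff / (epochs$rate / 2), type = "low")
  lp <- x
  for (r in seq_len(d[1])) for (c in seq_len(d[2]))
    lp[r, c, ] <- signal::filtfilt(bf, x[r, c, ])
  sidx <- time_indices(t, spont_window)
  eidx <- time_indices(t, evoked_window)
  sp <- mean(apply(lp[, , sidx, drop = FALSE], c(1, 2), rms))
  ev <- mean(apply(lp[, , eidx, drop = FALSE], c(1, 2), rms))
  ens <- apply(lp, c(2, 3), mean)
  midx <- time_indices(t, max_window)
  peak <- apply(ens[, midx, drop = FALSE], 1, function(v) {
    i <- which.max(abs(v)); c(abs(v[i]), t[midx][i])
  })
  structure(list(sp_rms = sp, ev_rms = ev,
                 sc_max_amp = stats::setNames(peak[1, ], epochs$channel_labels),
                 sc_max_latency = stats::setNames(peak[2, ], epochs$channel_labels),
                 sc_max_amp_mean = mean(peak[1, ]),
                 sc_max_latency_mean = mean(peak[2, ]),
                 cutoff = cutoff), class = "slow_component")
}

# Band-averaged dB time series for one channel of a (masked) power map.
channel_band_series <- function(powermap, channel, band) {
  fidx <- band_indices(powermap$freqs, band)
  ch <- channel
  if (is.character(ch)) ch <- match(ch, powermap$channel_labels)
  if (is.na(ch)) stop("unknown channel")
  colMeans(matrix(powermap$db[ch, fidx, ], length(fidx)))
}

#' Detect the OFF period (high-frequency suppression) on one channel
#'
#' On the channel's HF-band-averaged (default 20-40 Hz) significant dB series,
#' locates the period of power suppression (< 0 dB) within 0-0.3 s: the start
#' is the time of the first sample below 0 (the first downward zero crossing;
#' 0 if the series starts negative), the end is the time of the first
#' non-negative sample after the last suppressed one (the last upward zero
#' crossing; the window end if still suppressed there). Also reports the
#' minimum dB peak and its latency, and the mean HF dB in the fixed 0.08-0.18 s
#' quantification window. Non-detection (series never below 0) is a valid
#' result.
#'
#' @param powermap a masked `power_map` from [bootstrap_mask_power()].
#' @param channel channel index or label.
#' @param band HF band (default 20-40 Hz).
#' @param window detection window (default 0-0.3 s).
#' @param mean_window fixed quantification window (default 0.08-0.18 s).
#' @return Object of class `off_period`: `detected`, `start_s`, `end_s`,
#'   `min_db`, `min_latency_s`, `mean_hf_db`.
#' @export
detect_hf_suppression <- function(powermap, channel, band = c(20, 40),
                                  window = c(0, 0.3), mean_window = c(0.08, 0.18)) {
  if (is.null(powermap$mask)) stop("detect_hf_suppression needs a masked power map")
  s_full <- channel_band_series(powermap, channel, band)
  widx <- time_indices(powermap$times, window)
  s <- s_full[widx]; tt <- powermap$times[widx]
  ch <- if (is.character(channel)) channel else powermap$channel_labels[channel]
  midx <- time_indices(powermap$times, mean_window)
  mean_hf <- mean(s_full[midx])
  neg <- s < 0
  if (!any(neg)) {
    return(structure(list(detected = FALSE, start_s = NA_real_, end_s = NA_real_,
                          min_db = min(s), min_latency_s = tt[which.min(s)],
                          mean_hf_db = mean_hf, channel = ch),
                     class = "off_period"))
  }
  start_s <- tt[which(neg)[1]]
  last_neg <- max(which(neg))
  end_s <- if (last_neg < length(s)) tt[last_neg + 1] else window[2]
  structure(list(detected = TRUE, start_s = start_s, end_s = end_s,
                 min_db = min(s), min_latency_s = tt[which.min(s)],
                 mean_hf_db = mean_hf, channel = ch),
            class = "off_period")
}

#' @export
print.off_period <- function(x, ...) {
  if (x$detected)
    cat("<off_period> ", x$channel, ": ", sprintf("%.3f-%.3f s, min %.2f dB @ %.3f s, mean HF %.2f dB\n",
        x$start_s, x$end_s, x$min_db, x$min_latency_s, x$mean_hf_db), sep = "")
  else
    cat("<off_period> ", x$channel, ": not detected (mean HF ",
        sprintf("%.2f", x$mean_hf_db), " dB)\n", sep = "")
  invisible(x)
}

#' OFF-period summary across channels
#'
#' Runs [detect_hf_suppression()] on every channel and aggregates: statistics
#' averaged over channels with a detection, plus the fraction detected.
#'
#' @inheritParams detect_hf_suppression
#' @return list with `per_channel` (list of `off_period`), `fraction_detected`,
#'   `start_s`, `end_s`, `min_db`, `mean_hf_db` (means over detected channels;
#'   `mean_hf_db` over all channels).
#' @export
off_period_summary <- function(powermap, band = c(20, 40), window = c(0, 0.3),
                               mean_window = c(0.08, 0.18)) {
  per <- lapply(seq_along(powermap$channel_labels), function(ch)
    detect_hf_suppression(powermap, ch, band, window, mean_window))
  det <- vapply(per, `[[`, TRUE, "detected")
  pick <- function(f) vapply(per, `[[`, 0, f)
  list(per_channel = per,
       fraction_detected = mean(det),
       start_s = if (any(det)) mean(pick("start_s")[det]) else NA_real_,
       end_s = if (any(det)) mean(pick("end_s")[det]) else NA_real_,
       min_db = if (any(det)) mean(pick("min_db")[det]) else NA_real_,
       mean_hf_db = mean(pick("mean_hf_db")))
}

#' Detect late high-frequency activations
#'
#' Per channel, the earliest time in the search window (default 0.08-0.8 s)
#' where the significant HF-band mean dB exceeds 0; the late-HF probability is
#' the fraction of channels with such an onset.
#'
#' @param powermap a masked `power_map`.
#' @param band HF band (default 20-40 Hz).
#' @param window search window in seconds.
#' @return list with `onset_s` (per channel, NA when none) and `probability`.
#' @export
detect_late_hf <- function(powermap, band = c(20, 40), window = c(0.08, 0.8)) {
  if (is.null(powermap$mask)) stop("detect_late_hf needs a masked power map")
  widx <- which(powermap$times >= window[1] - 1e-9 & powermap$times <= window[2] + 1e-9)
  onsets <- vapply(seq_along(powermap$channel_labels), function(ch) {
    s <- channel_band_series(powermap, ch, band)[widx]
    i <- which(s > 0)
    if (length(i)) powermap$times[widx][i[1]] else NA_real_
  }, 0)
  names(onsets) <- powermap$channel_labels
  list(onset_s = onsets, probability = mean(!is.na(onsets)))
}

#' Low-frequency power features of the evoked response
#'
#' Mean significant LF (default 1-4 Hz) dB over 0-0.5 s and the latency of the
#' maximal positive LF dB peak within 0-0.6 s, per channel then averaged
#' (channels without a positive value report no peak).
#'
#' @param powermap a masked `power_map`.
#' @param band LF band.
#' @param mean_window window for the mean (default 0-0.5 s).
#' @param peak_window window for the positive peak (default 0-0.6 s).
#' @return list with `mean_lf_db`, `peak_latency_s` (per channel, NA if no
#'   positive value), `peak_latency_mean` (over channels with a peak),
#'   `peak_db` per channel.
#' @export
lf_features <- function(powermap, band = c(1, 4), mean_window = c(0, 0.5),
                        peak_window = c(0, 0.6)) {
  if (is.null(powermap$mask)) stop("lf_features needs a masked power map")
  nch <- length(powermap$channel_labels)
  midx <- time_indices(powermap$times, mean_window)
  pidx <- time_indices(powermap$times, peak_window)
  means <- numeric(nch); lat <- rep(NA_real_, nch); pk <- rep(NA_real_, nch)
  for (ch in seq_len(nch)) {
    s <- channel_band_series(powermap, ch, band)
    means[ch] <- mean(s[midx])
    sp <- s[pidx]
    if (any(sp > 0)) {
      i <- which.max(sp)
      lat[ch] <- powermap$times[pidx][i]
      pk[ch] <- sp[i]
    }
  }
  list(mean_lf_db = mean(means), mean_lf_db_per_channel = means,
       peak_latency_s = stats::setNames(lat, powermap$channel_labels),
       peak_db = stats::setNames(pk, powermap$channel_labels),
       peak_latency_mean = if (any(!is.na(lat))) mean(lat, na.rm = TRUE) else NA_real_)
}
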