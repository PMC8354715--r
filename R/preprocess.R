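#' Condition a continuous session: re-reference, band-pass, resample
#'
#' Re-references the signal (common average for evoked-response analysis, or a
#' bipolar derivation for spontaneous activity), applies a zero-phase
#' (forward-backward) Butterworth band-pass, and resamples to the analysis rate
#' with a polyphase anti-aliased resampler.
#'
#' @param session an [eeg_session()].
#' @param reference_scheme `"common_average"`, `"raw"` (leave as is), or
#'   `"bipolar"` with `pair` naming two channels (output is a single derived
#'   channel `a-b`).
#' @param pair character vector of two channel labels for the bipolar scheme.
#' @param band band-pass edges in Hz (default 0.5-80).
#' @param order Butterworth order (default 3; applied forward and backward).
#' @param target_rate output sampling rate (default 500 samples/s).
#' @return A conditioned [eeg_session()] with updated `rate` and `reference`.
#' @export
condition_signal <- function(session, reference_scheme = c("common_average", "raw", "bipolar"),
                             pair = NULL, band = c(0.5, 80), order = 3,
                             target_rate = 500) {
  reference_scheme <- match.arg(reference_scheme)
  validate_session(session)
  if (session$rate < 2 * band[2])
    stop("sampling rate ", session$rate, " cannot represent the band up to ", band[2], " Hz")
  if (target_rate > session$rate)
    stop("target_rate (", target_rate, ") exceeds the session rate (", session$rate, ")")
  sig <- session$signal
  labels <- session$channel_labels
  xy <- session$channel_xy
  reference <- session$reference
  if (reference_scheme == "common_average") {
    sig <- sweep(sig, 2, colMeans(sig))
    reference <- "common_average"
  } else if (reference_scheme == "bipolar") {
    if (is.null(pair) || length(pair) != 2)
      stop("bipolar referencing needs pair = c(a, b)")
    miss <- setdiff(pair, labels)
    if (length(miss)) stop("bipolar scheme names absent channel(s): ",
                           paste(miss, collapse = ", "))
    ia <- match(pair[1], labels); ib <- match(pair[2], labels)
    sig <- matrix(sig[ia, ] - sig[ib, ], nrow = 1)
    labels <- paste0(pair[1], "-", pair[2])
    xy <- matrix(colMeans(session$channel_xy[c(ia, ib), , drop = FALSE]), 1)
    reference <- sprintf("bipolar(%s-%s)", pair[1], pair[2])
  }
  bf <- signal::butter(order, band / (session$rate / 2), type = "pass")
  for (i in seq_len(nrow(sig))) sig[i, ] <- signal::filtfilt(bf, sig[i, ])
  rate <- session$rate
  if (target_rate != rate) {
    frac <- ratio_int(target_rate, rate)
    sig2 <- t(apply(sig, 1, function(x) signal::resample(x, frac[1], frac[2])))
    if (nrow(sig) == 1) sig2 <- matrix(sig2, nrow = 1)
    sig <- sig2
    rate <- target_rate
  }
  out <- session
  out$signal <- sig
  out$rate <- rate
  out$channel_labels <- labels
  out$channel_xy <- xy
  out$reference <- reference
  out
}

# Reduce target/source rate to an integer p/q ratio.
ratio_int <- function(p, q) {
  scale <- 1e6
  p <- round(p * scale); q <- round(q * scale)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Epoch a session around stimulus onsets and offset-correct the baseline
#'
#' Cuts one epoch per event on the session's sample grid and subtracts, per
#' trial and channel, the mean voltage of the baseline window. Events too close
#' to the recording edges are reported (message + `skipped_events` in the
#' provenance) and skipped.
#'
#' @param session a conditioned [eeg_session()].
#' @param window epoch extent in seconds relative to stimulus (default -5 to 5;
#'   closed-left, open-right on the sample grid, so a 10 s epoch at 500 Hz has
#'   exactly 5000 samples and t = 0 is the first response sample).
#' @param baseline offset-correction window (default -1 to 0 s).
#' @return An [eeg_epochs()] object.
#' @export
epoch_and_correct <- function(session, window = c(-5, 5), baseline = c(-1, 0)) {
  validate_session(session)
  rate <- session$rate
  n <- round((window[2] - window[1]) * rate)
  time_axis <- window[1] + (seq_len(n) - 1) / rate
  rel <- round(window[1] * rate) + (seq_len(n) - 1)   # sample offsets from onset
  onsets_idx <- round(session$events$onset_s * rate)  # 0-based index of t = 0
  ok <- (onsets_idx + rel[1] >= 0) & (onsets_idx + rel[n] <= ncol(session$signal) - 1)
  if (any(!ok)) {
    skipped <- which(!ok)
    message("skipping ", length(skipped), " event(s) too close to the recording edge: ",
            paste(round(session$events$onset_s[skipped], 3), collapse = ", "), " s")
  } else skipped <- integer(0)
  keep_ev <- which(ok)
  if (length(keep_ev) == 0) stop("no event has enough signal on both sides")
  nch <- nrow(session$signal)
  data <- array(0, dim = c(length(keep_ev), nch, n))
  for (k in seq_along(keep_ev)) {
    idx <- onsets_idx[keep_ev[k]] + rel + 1
    data[k, , ] <- session$signal[, idx]
  }
  bidx <- time_indices(time_axis, baseline)
  bmean <- apply(data[, , bidx, drop = FALSE], c(1, 2), mean)
  data <- data - array(bmean, dim = dim(data))   # recycles over time, dims align
  eeg_epochs(data, time_axis, rate,
             channel_labels = session$channel_labels,
             channel_xy = session$channel_xy,
             state = session$state,
             provenance = list(window = window, baseline = baseline,
                               reference = session$reference,
                               skipped_events = skipped,
                               intensity_uA = session$events$intensity_uA[keep_ev]))
}

#' Interpolate the stimulus artifact within an epoch window
#'
#' Replaces samples inside the artifact window (default 0 to 0.005 s,
#' inclusive) with a cubic spline fitted on 10 anchor samples on each side;
#' samples outside the window are untouched.
#'
#' @param epochs an [eeg_epochs()].
#' @param window artifact window in seconds (closed on both ends).
#' @param n_anchor anchor samples per side (default 10).
#' @return The epochs with the window interpolated; parameters appended to
#'   provenance.
#' @export
interpolate_stim_artifact <- function(epochs, window = c(0, 0.005), n_anchor = 10) {
  t <- epochs$time_axis
  win <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(win) == 0) stop("artifact window contains no samples")
  if (win[1] - n_anchor < 1 || win[length(win)] + n_anchor > length(t))
    stop("artifact window (plus anchors) exceeds the epoch")
  anchors <- c(win[1] - (n_anchor:1), win[length(win)] + (1:n_anchor))
  d <- dim(epochs$data)
  for (r in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      sf <- splinefun(t[anchors], epochs$data[r, c, anchors], method = "fmm")
      epochs$data[r, c, win] <- sf(t[win])
    }
  }
  epochs$provenance$artifact_window <- window
  epochs$provenance$artifact_anchors <- n_anchor
  epochs
}

#' Reject trials with high-voltage baseline artifacts
#'
#' Computes, per trial, the rms of the baseline samples pooled over channels
#' (rms of the concatenated channel baselines) and rejects trials whose rms
#' strictly exceeds mean + 3 SD across trials. With zero SD (identical trials)
#' nothing is rejected.
#'
#' @param epochs an [eeg_epochs()].
#' @param baseline baseline window (default -1 to 0 s).
#' @return A list with `epochs` (kept_mask updated) and `report` (class
#'   `rejection_report`: per-trial rms, threshold, rejected indices).
#' @export
reject_trials <- function(epochs, baseline = c(-1, 0)) {
  d <- dim(epochs$data)
  if (d[1] < 2) stop("trial rejection needs at least 2 trials (SD undefined)")
  bidx <- time_indices(epochs$time_axis, baseline)
  trial_rms <- vapply(seq_len(d[1]),
                      function(r) rms(as.numeric(epochs$data[r, , bidx])), 0)
  threshold <- mean(trial_rms) + 3 * sd(trial_rms)
  rejected <- which(trial_rms > threshold)
  epochs$kept_mask <- epochs$kept_mask & !(seq_len(d[1]) %in% rejected)
  epochs$provenance$rejection <- list(baseline = baseline, threshold = threshold,
                                      rejected = rejected)
  report <- structure(list(trial_rms = trial_rms, threshold = threshold,
                           rejected = rejected, baseline = baseline),
                      class = "rejection_report")
  list(epochs = epochs, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat("<rejection_report> threshold ", sprintf("%.3f", x$threshold), " uV; ",
      length(x$rejected), "/", length(x$trial_rms), " trials rejected\n", sep = "")
  invisible(x)
}
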