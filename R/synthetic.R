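#' State template for the synthetic-session generator
#'
#' Encodes the statistical structure the analysis assumes for each brain
#' state: a 1/f background with a state-dependent spectral exponent, a
#' phase-locked evoked response (early deflection, per-channel oscillation
#' bank, slow component, occipital coupling bank) whose locked duration
#' depends on the state, and multiplicative high-frequency (> 15 Hz) gain
#' profiles realizing the OFF period (suppression), the sustained HF
#' activation of wakefulness and late non-locked HF bursts. Amplitudes decay
#' exponentially with grid distance from the stimulation site.
#'
#' Defaults (per state): background exponent -1.4 (wake), -3.0
#' (propofol/sevoflurane), -1.0 (ketamine); locked duration 0.32 / 0.13 /
#' 0.13 / 0.23 s; OFF period absent in wake and -3 dB over 0.08-0.18 s under
#' anesthesia; sustained +4.1 dB HF gain (0.04-0.55 s) in wake only; late HF
#' burst probability 0 (wake; its sustained gain already covers the late
#' window) / 0.33 / 0.33 / 0.9.
#'
#' @param state one of "wake", "propofol", "sevoflurane", "ketamine", "noise"
#'   ("noise" has no evoked response at all).
#' @param ... named overrides of any template field.
#' @return list of class `state_template`.
#' @export
state_template <- function(state = c("wake", "propofol", "sevoflurane",
                                     "ketamine", "noise"), ...) {
  state <- match.arg(state)
  base <- list(
    state = state,
    exponent = -1.4, bg_rms_uV = 30,
    early_amp_uV = 150, early_freq = 30, early_window = c(0.006, 0.03),
    osc_amp_uV = 40, osc_freq_range = c(8, 25), locked_dur_s = 0.32,
    phase_jitter_sd = 0.3,
    sc_amp_uV = 40, sc_peak_s = 0.15,
    off_depth_db = NA_real_, off_window = c(0.08, 0.18),
    hf_gain_db = 0, hf_gain_window = c(0.04, 0.55),
    late_hf_prob = 0, late_hf_gain_db = 4, late_hf_onset_range = c(0.25, 0.45),
    late_hf_dur_s = 0.15,
    couple_channels = c("V2L", "V2R", "V1L", "V1R"), couple_freq = 10,
    couple_amp_uV = 30, couple_offsets = c(0, pi / 2, pi, 3 * pi / 2),
    couple_jitter_sd = 0.2,
    decay_mm = 6, hf_split_hz = 15, knee_hz = 4
  )
  presets <- switch(state,
    wake = list(hf_gain_db = 4.1),
    propofol = list(exponent = -3.0, bg_rms_uV = 60, locked_dur_s = 0.13,
                    osc_freq_range = c(8, 10), osc_amp_uV = 25,
                    couple_amp_uV = 20,
                    sc_amp_uV = 60, sc_peak_s = 0.13, off_depth_db = -3,
                    late_hf_prob = 0.33, late_hf_onset_range = c(0.3, 0.45),
                    late_hf_gain_db = 3),
    sevoflurane = list(exponent = -3.0, bg_rms_uV = 60, locked_dur_s = 0.13,
                       osc_freq_range = c(8, 10), osc_amp_uV = 25,
                       couple_amp_uV = 20,
                       sc_amp_uV = 60, sc_peak_s = 0.13, off_depth_db = -3,
                       late_hf_prob = 0.33, late_hf_onset_range = c(0.3, 0.45),
                       late_hf_gain_db = 3),
    ketamine = list(exponent = -1.0, locked_dur_s = 0.23,
                    osc_freq_range = c(8, 10), osc_amp_uV = 30,
                    couple_amp_uV = 20, sc_amp_uV = 50,
                    sc_peak_s = 0.14, off_depth_db = -3, late_hf_prob = 0.9,
                    late_hf_onset_range = c(0.25, 0.45)),
    noise = list(early_amp_uV = 0, osc_amp_uV = 0, sc_amp_uV = 0,
                 couple_amp_uV = 0, locked_dur_s = 0)
  )
  tpl <- utils::modifyList(base, presets)
  tpl <- utils::modifyList(tpl, list(...))
  validate_template(tpl)
  structure(tpl, class = "state_template")
}

validate_template <- function(tpl) {
  if (tpl$locked_dur_s < 0 || tpl$locked_dur_s > 0.8)
    stop("locked duration must be in [0, 0.8] s")
  amps <- c(tpl$bg_rms_uV, tpl$early_amp_uV, tpl$osc_amp_uV, tpl$sc_amp_uV,
            tpl$couple_amp_uV)
  if (any(amps < 0)) stop("amplitudes must be nonnegative")
  if (tpl$late_hf_prob < 0 || tpl$late_hf_prob > 1)
    stop("late_hf_prob must be a probability")
  if (tpl$decay_mm <= 0) stop("decay_mm must be positive")
  if (tpl$bg_rms_uV <= 0) stop("background rms must be positive")
  invisible(tpl)
}

# Squared magnitude response of the forward-backward 3rd-order Butterworth
# 0.5-80 Hz band-pass at the given frequencies (amplitude factor of filtfilt).
bandpass_mag2 <- function(f, rate) {
  bf <- signal::butter(3, c(0.5, 80) / (rate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / rate)
  num <- Reduce(function(acc, b) acc * z + b, bf$b, accumulate = FALSE)
  den <- Reduce(function(acc, a) acc * z + a, bf$a, accumulate = FALSE)
  Mod(num / den)^2
}

# Raised-cosine window profile on a time axis: 1 inside [w1, w2] with
# half-cosine ramps (possibly asymmetric, ramp = c(up, down)) just inside the
# edges, 0 outside.
smooth_window <- function(t, w, ramp = 0.02) {
  ramp <- rep(ramp, length.out = 2)
  ramp <- pmin(ramp, diff(w) / 2)
  out <- numeric(length(t))
  inside <- t >= w[1] & t <= w[2]
  out[inside] <- 1
  if (ramp[1] > 0) {
    up <- inside & t < w[1] + ramp[1]
    out[up] <- 0.5 - 0.5 * cos(pi * (t[up] - w[1]) / ramp[1])
  }
  if (ramp[2] > 0) {
    dn <- inside & t > w[2] - ramp[2]
    out[dn] <- 0.5 - 0.5 * cos(pi * (w[2] - t[dn]) / ramp[2])
  }
  out
}

#' Simulate one stimulation session with full ground truth
#'
#' Background noise is generated by inverse-FFT spectral shaping of white
#' noise to the template's exponent and split at 15 Hz; the > 15 Hz part is
#' multiplied by the state's gain profiles (OFF-period suppression, sustained
#' or late HF activations). The evoked response is added from t = 0: a locked
#' early deflection, a per-channel oscillation bank (8-25 Hz) whose phase is
#' shared across trials for the locked duration, a slow-component half-wave,
#' and the occipital coupling bank. All draws are recorded in the ground
#' truth; identical seeds give bit-identical output.
#'
#' @param template a [state_template()].
#' @param n_trials trials (default 90).
#' @param n_channels channels (default 16, the standard montage).
#' @param rate sampling rate (default 500 samples/s).
#' @param epoch epoch window in seconds (default -5 to 5).
#' @param seed RNG seed (required).
#' @param channel_gain optional per-channel multiplicative gain (used by
#'   [paired_conditions()] to share structure within a pair).
#' @param return `"epochs"` (default) or `"session"` (continuous signal with
#'   one event per trial).
#' @return list with `epochs` (or `session`) and `ground_truth`.
#' @export
simulate_session <- function(template, n_trials = 90, n_channels = 16,
                             rate = 500, epoch = c(-5, 5), seed,
                             channel_gain = NULL, return = c("epochs", "session")) {
  validate_template(template)
  return <- match.arg(return)
  if (n_trials < 1 || n_channels < 2) stop("need >= 1 trial and >= 2 channels")
  nt <- round((epoch[2] - epoch[1]) * rate)
  t <- epoch[1] + (seq_len(nt) - 1) / rate
  if (n_channels == 16) {
    mont <- rat_montage()
  } else {
    mont <- data.frame(label = paste0("ch", seq_len(n_channels)),
                       x_mm = rep(c(-1.5, 1.5), length.out = n_channels),
                       y_mm = 5 - 1.5 * (seq_len(n_channels) - 1))
  }
  stim <- stim_site()
  dist <- sqrt((mont$x_mm - stim["x_mm"])^2 + (mont$y_mm - stim["y_mm"])^2)
  decay <- exp(-dist / template$decay_mm)
  if (is.null(channel_gain)) channel_gain <- rep(1, n_channels)
  stopifnot(length(channel_gain) == n_channels)

  out <- with_seed(seed, {
    osc_freq <- template$osc_freq_range[1] +
      diff(template$osc_freq_range) * (seq_len(n_channels) - 1) / max(1, n_channels - 1)
    osc_phase <- runif(n_channels, 0, 2 * pi)
    late_ch <- runif(n_channels) < template$late_hf_prob
    late_onset <- runif(n_channels, template$late_hf_onset_range[1],
                        template$late_hf_onset_range[2])
    # spectral shaping: 1/f^|exponent| above the low-frequency knee, plateau
    # below it (unbounded DC power is unphysical), times the squared magnitude
    # of the 0.5-80 Hz zero-phase band-pass the preprocessing would apply --
    # the generator emulates preprocessed signal.
    fax <- pmin(seq_len(nt) - 1, nt - (seq_len(nt) - 1)) * rate / nt
    shape <- pmax(fax, template$knee_hz)^(template$exponent / 2)
    shape[1] <- 0
    shape <- shape * bandpass_mag2(fax, rate)
    lo_mask <- fax <= template$hf_split_hz
    # per-channel HF gain profile (amplitude = 10^(dB/20), dB on power)
    resp <- t >= 0
    gain_profiles <- lapply(seq_len(n_channels), function(c) {
      g <- rep(1, nt)
      if (template$hf_gain_db != 0)
        g <- g * (1 + (10^(template$hf_gain_db / 20) - 1) *
                    smooth_window(t, template$hf_gain_window))
      if (!is.na(template$off_depth_db))
        g <- g * (1 + (10^(template$off_depth_db / 20) - 1) *
                    smooth_window(t, template$off_window, ramp = 0.005))
      if (late_ch[c])
        g <- g * (1 + (10^(template$late_hf_gain_db / 20) - 1) *
                    smooth_window(t, c(late_onset[c], late_onset[c] + template$late_hf_dur_s)))
      g[!resp] <- 1
      g
    })
    # locked-oscillation envelope: fast onset, damped tail ending at the
    # locked duration (its midpoint marks the fading of coherent drive)
    env <- if (template$locked_dur_s > 0)
      smooth_window(t, c(0, template$locked_dur_s),
                    ramp = c(min(0.02, template$locked_dur_s / 3),
                             min(0.08, template$locked_dur_s / 2)))
    else numeric(nt)
    # locked early deflection and slow component (identical across trials)
    ew <- template$early_window
    early <- sin(2 * pi * template$early_freq * (t - ew[1])) *
      smooth_window(t, ew, ramp = diff(ew) / 3)
    sc <- numeric(nt)
    sidx <- t >= 0 & t <= 2 * template$sc_peak_s
    sc[sidx] <- sin(pi * t[sidx] / (2 * template$sc_peak_s))
    data <- array(0, dim = c(n_trials, n_channels, nt))
    cpl_idx <- match(template$couple_channels, mont$label)
    cpl_idx <- cpl_idx[!is.na(cpl_idx)]
    for (c in seq_len(n_channels)) {
      white <- matrix(rnorm(nt * n_trials), nt, n_trials)
      W <- mvfft(white) * shape
      low <- Re(mvfft(W * lo_mask, inverse = TRUE)) / nt
      high <- Re(mvfft(W * (!lo_mask), inverse = TRUE)) / nt
      scl <- template$bg_rms_uV / sqrt(colMeans((low + high)^2))
      low <- low * rep(scl, each = nt)
      high <- (high * rep(scl, each = nt)) * gain_profiles[[c]]
      amp <- channel_gain[c] * decay[c]
      det <- amp * (template$early_amp_uV * early + template$sc_amp_uV * sc)
      jit <- rnorm(n_trials, 0, template$phase_jitter_sd)
      carrier_c <- env * cos(2 * pi * osc_freq[c] * t + osc_phase[c])
      carrier_s <- env * sin(2 * pi * osc_freq[c] * t + osc_phase[c])
      osc <- amp * template$osc_amp_uV *
        (carrier_c %o% cos(jit) - carrier_s %o% sin(jit))
      sig <- low + high + det + osc
      if (c %in% cpl_idx && template$couple_amp_uV > 0) {
        off <- template$couple_offsets[match(c, cpl_idx)]
        jit2 <- rnorm(n_trials, 0, template$couple_jitter_sd)
        cc <- env * cos(2 * pi * template$couple_freq * t + off)
        cs <- env * sin(2 * pi * template$couple_freq * t + off)
        sig <- sig + channel_gain[c] * template$couple_amp_uV *
          (cc %o% cos(jit2) - cs %o% sin(jit2))
      } else if (template$couple_amp_uV > 0) {
        rnorm(n_trials)  # keep the draw stream aligned across channel sets
      }
      data[, c, ] <- t(sig)
    }
    list(data = data, osc_freq = osc_freq, osc_phase = osc_phase,
         late_ch = late_ch, late_onset = late_onset)
  })

  # per-trial, per-channel baseline offset correction (-1..0 s), as the
  # preprocessing the generator emulates would apply
  bidx <- time_indices(t, c(-1, 0))
  bmean <- apply(out$data[, , bidx, drop = FALSE], c(1, 2), mean)
  out$data <- out$data - array(bmean, dim = dim(out$data))

  gt <- list(template = unclass(template), seed = seed,
             n_trials = n_trials, n_channels = n_channels, rate = rate,
             osc_freq_hz = out$osc_freq, osc_phase_rad = out$osc_phase,
             channel_gain = channel_gain, distance_mm = dist,
             decay = decay, late_hf_channels = which(out$late_ch),
             late_hf_onset_s = out$late_onset[out$late_ch])
  epochs <- eeg_epochs(out$data, t, rate,
                       channel_labels = mont$label,
                       channel_xy = as.matrix(mont[, c("x_mm", "y_mm")]),
                       state = if (template$state == "noise") "synthetic" else template$state,
                       provenance = list(synthetic = TRUE, seed = seed))
  if (return == "epochs") return(list(epochs = epochs, ground_truth = gt))
  sig <- matrix(0, n_channels, n_trials * nt)
  for (r in seq_len(n_trials))
    sig[, (r - 1) * nt + seq_len(nt)] <- out$data[r, , ]
  onsets <- -epoch[1] + (seq_len(n_trials) - 1) * (epoch[2] - epoch[1])
  sess <- eeg_session(sig, rate, channel_labels = mont$label,
                      channel_xy = as.matrix(mont[, c("x_mm", "y_mm")]),
                      events = data.frame(onset_s = onsets,
                                          intensity_uA = rep(50, n_trials)),
                      state = if (template$state == "noise") "synthetic" else template$state,
                      reference = "common_average", seed = seed)
  list(session = sess, ground_truth = gt)
}

#' Paired wake/anesthesia synthetic sessions
#'
#' Emulates the within-animal design: each pair shares structural randomness
#' (per-channel gains, drawn log-normally) while trial noise is independent;
#' all child seeds derive deterministically from the master seed.
#'
#' @param wake_template,anesthesia_template [state_template()] objects.
#' @param n_pairs number of pairs (9 reproduces the study's group geometry).
#' @param seed master seed.
#' @param gain_sd SD of the shared log-normal channel gains (default 0.2).
#' @param ... passed to [simulate_session()] (e.g. `n_trials`).
#' @return list of length `n_pairs`; each element has `wake` and `anesthesia`
#'   simulation results (as returned by [simulate_session()]).
#' @export
paired_conditions <- function(wake_template, anesthesia_template, n_pairs,
                              seed, gain_sd = 0.2, ...) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  validate_template(wake_template)
  validate_template(anesthesia_template)
  seeds <- derive_seeds(seed, 3 * n_pairs)
  dots <- list(...)
  nch <- if (is.null(dots$n_channels)) 16 else dots$n_channels
  lapply(seq_len(n_pairs), function(p) {
    gains <- with_seed(seeds[3 * p - 2], exp(rnorm(nch, 0, gain_sd)))
    list(
      wake = simulate_session(wake_template, seed = seeds[3 * p - 1],
                              channel_gain = gains, ...),
      anesthesia = simulate_session(anesthesia_template, seed = seeds[3 * p],
                                    channel_gain = gains, ...)
    )
  })
}
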