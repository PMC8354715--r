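#' Run the full evoked-response analysis on one epoch set
#'
#' Orchestrates the standard pipeline: trial rejection, Morlet decomposition
#' (40 wavelets, 1-40 Hz, coefficients retained on a cropped, decimated grid),
#' bootstrap-masked dB power and ITPC, OFF-period and late-HF detection, LF
#' features, ITPC drop times, ISPC connectivity degree in the two analysis
#' windows, PCI-ST (full and 0.08-0.6 s response windows), early ERP rms, the
#' slow component, and the spectral exponent of the pre-stimulus activity.
#'
#' @param epochs an [eeg_epochs()] covering -5 to 5 s at 500 samples/s.
#' @param seed master seed for all bootstrap draws.
#' @param tf_crop,tf_decimate retained time-frequency grid (defaults: -0.6 to
#'   0.85 s at 100 Hz), chosen to cover every analysis window while bounding
#'   memory.
#' @param n_perm bootstrap permutations (default 500).
#' @param reject apply baseline-rms trial rejection first (default TRUE).
#' @param spectrum_channels channel pair for the spontaneous-activity bipolar
#'   derivation (default M2aR-V2R when present, else channel 1).
#' @return list of class `session_features` with the fitted objects and scalar
#'   features (`hf_db`, `itpc_drop_s`, `cd_hf`, `cd_post`, `pcist_0_0.6`,
#'   `pcist_0.08_0.6`, `spectral_exponent`, ...).
#' @export
analyze_session <- function(epochs, seed, tf_crop = c(-0.6, 0.85),
                            tf_decimate = 5L, n_perm = 500, reject = TRUE,
                            spectrum_channels = NULL) {
  seeds <- derive_seeds(seed, 3)
  if (reject && dim(epochs$data)[1] >= 2) {
    rej <- reject_trials(epochs)
    epochs <- rej$epochs
  } else rej <- NULL
  tf <- morlet_tf(epochs, crop = tf_crop, decimate = tf_decimate)
  pw <- bootstrap_mask_power(tf, n_perm = n_perm, seed = seeds[1])
  itm <- itpc_mask(itpc_map(tf), tf, n_perm = n_perm, seed = seeds[2])
  drops <- drop_times(itm)
  offs <- off_period_summary(pw)
  late <- detect_late_hf(pw)
  lf <- lf_features(pw)
  isp <- ispc_significant(ispc_map(tf, band = c(5, 14)), n_perm = n_perm,
                          seed = seeds[3])
  cd_hf <- connectivity_degree(isp, window = c(0.08, 0.18))
  cd_post <- connectivity_degree(isp, window = c(0.18, 0.30))
  pci_full <- pcist(epochs)
  p2 <- pcist_params(response = c(0.08, 0.6))
  pci_late <- pcist(epochs, params = p2)
  early <- early_erp_rms(epochs)
  sc <- slow_component(epochs)
  if (is.null(spectrum_channels)) {
    spectrum_channels <- if (all(c("M2aR", "V2R") %in% epochs$channel_labels))
      c("M2aR", "V2R") else 1
  }
  spec <- periodogram_mean(epochs, channels = spectrum_channels)
  structure(list(
    rejection = if (is.null(rej)) NULL else rej$report,
    power = pw, itpc = itm, drops = drops, off = offs, late_hf = late,
    lf = lf, ispc = isp, cd_hf = cd_hf, cd_post = cd_post,
    pcist_full = pci_full, pcist_late = pci_late,
    early_erp = early, slow = sc, spectrum = spec,
    hf_db = band_average(pw, c(20, 40), c(0.08, 0.18)),
    itpc_drop_s = drops$drop_mean,
    cd_hf_mean = cd_hf$cd_mean, cd_post_mean = cd_post$cd_mean,
    pcist_0_0.6 = pci_full$value, pcist_0.08_0.6 = pci_late$value,
    spectral_exponent = spectral_exponent(spec),
    late_hf_probability = late$probability,
    state = epochs$state, seed = seed
  ), class = "session_features")
}

#' @export
print.session_features <- function(x, ...) {
  cat("<session_features> state ", x$state, "\n", sep = "")
  cat(sprintf("  PCI-ST (0.08-0.6 s): %.2f | ITPC drop: %.3f s | HF (0.08-0.18 s): %.2f dB\n",
              x$pcist_0.08_0.6, x$itpc_drop_s, x$hf_db))
  cat(sprintf("  CD 0.08-0.18 s: %.3f | CD 0.18-0.3 s: %.3f | exponent: %.2f | late-HF p: %.2f\n",
              x$cd_hf_mean, x$cd_post_mean, x$spectral_exponent,
              x$late_hf_probability))
  invisible(x)
}

#' One-row feature summary for tabular export
#'
#' @param features a `session_features` object.
#' @return single-row data.frame of the scalar features.
#' @export
features_row <- function(features) {
  data.frame(
    state = features$state,
    pcist = features$pcist_0.08_0.6,
    pcist_full = features$pcist_0_0.6,
    n_components = features$pcist_late$n_components,
    itpc_drop_s = features$itpc_drop_s,
    hf_db = features$hf_db,
    cd_hf = features$cd_hf_mean,
    cd_post = features$cd_post_mean,
    spectral_exponent = features$spectral_exponent,
    early_erp_rms = features$early_erp$mean,
    sc_max_uV = features$slow$sc_max_amp_mean,
    late_hf_probability = features$late_hf_probability,
    off_fraction = features$off$fraction_detected,
    seed = features$seed
  )
}
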