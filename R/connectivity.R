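#' Intersite phase clustering (ISPC) for every channel pair
#'
#' For each unordered channel pair, the clustering over trials of the phase
#' difference at each frequency and time point: the modulus of the trial-mean
#' of `exp(i(kx - ky))`. 1 means the phase lag between the two channels is
#' identical in every trial.
#'
#' @param tf a [morlet_tf()] decomposition with at least 2 channels and trials.
#' @param band optional frequency band to restrict to (saves memory).
#' @return Object of class `ispc_map`: `ispc` (pairs x frequencies x time),
#'   `pairs` (2-column index matrix), `freqs`, `times`, plus the per-trial pair
#'   phasor sums needed later for the volume-conduction test.
#' @export
ispc_map <- function(tf, band = NULL) {
  d <- dim(tf$coef)
  if (d[2] < 2) stop("ISPC needs at least 2 channels")
  if (d[1] < 2) stop("ISPC needs at least 2 trials")
  fsel <- if (is.null(band)) seq_along(tf$freqs) else band_indices(tf$freqs, band)
  u <- unit_phasors(tf)[, , fsel, , drop = FALSE]
  pairs <- t(utils::combn(d[2], 2))
  np <- nrow(pairs)
  ispc <- array(0, dim = c(np, length(fsel), d[4]))
  dphasor <- array(0i, dim = c(d[1], np, length(fsel), d[4]))
  for (p in seq_len(np)) {
    dp <- u[, pairs[p, 1], , , drop = FALSE] * Conj(u[, pairs[p, 2], , , drop = FALSE])
    dim(dp) <- c(d[1], length(fsel), d[4])
    dphasor[, p, , ] <- dp
    ispc[p, , ] <- Mod(colMeans(dp))
  }
  structure(list(ispc = ispc, pairs = pairs, freqs = tf$freqs[fsel],
                 times = tf$times, n_trials = d[1],
                 channel_labels = tf$channel_labels,
                 dphasor = dphasor, corrected = NULL, mask = NULL,
                 excluded = NULL, boot = NULL), class = "ispc_map")
}

#' @export
print.ispc_map <- function(x, ...) {
  d <- dim(x$ispc)
  cat("<ispc_map> ", d[1], " pairs x ", d[2], " freqs x ", d[3], " samples (",
      x$n_trials, " trials); ",
      if (is.null(x$mask)) "raw" else "baseline-corrected + masked", "\n", sep = "")
  invisible(x)
}

# Gaussian v test statistic u for clustering of angles toward mu.
v_test_u <- function(phasors, mu) {
  n <- length(phasors)
  m <- mean(phasors)
  V <- n * Mod(m) * cos(Arg(m) - mu)
  V * sqrt(2 / n)
}

#' Significant ISPC variations with volume-conduction exclusion
#'
#' Subtracts the per-pair/frequency baseline mean, masks with a two-sided
#' bootstrap (per permutation one baseline time point per trial, percentile
#' thresholds at `alpha`), and excludes pairs whose trial phase-difference
#' distribution clusters toward 0 or pi (Gaussian v test on the per-trial mean
#' phase difference over each analysis window; such zero/pi-lag consistency is
#' the signature of volume conduction). Excluded entries are set to 0 in the
#' corresponding window.
#'
#' @param ispcmap an [ispc_map()].
#' @param baseline baseline window (default -0.5 to -0.2 s).
#' @param n_perm permutations (default 500).
#' @param alpha two-sided bootstrap level (default 0.05).
#' @param vtest_alpha one-sided v-test level toward each of 0 and pi (default
#'   0.05).
#' @param windows list of analysis windows for which exclusions are computed
#'   (default: 0.08-0.18 s and 0.18-0.3 s).
#' @param seed RNG seed.
#' @return The `ispc_map` with `corrected` (baseline-corrected, masked values;
#'   non-significant entries exactly 0), `mask`, and `excluded`
#'   (pairs x frequencies x windows logical).
#' @export
ispc_significant <- function(ispcmap, baseline = c(-0.5, -0.2), n_perm = 500,
                             alpha = 0.05, vtest_alpha = 0.05,
                             windows = list(c(0.08, 0.18), c(0.18, 0.30)),
                             seed) {
  if (n_perm < 1 / alpha) stop("n_perm too small to resolve alpha = ", alpha)
  bidx <- time_indices(ispcmap$times, baseline)
  d <- dim(ispcmap$ispc)  # pairs, freqs, time
  base <- apply(ispcmap$ispc[, , bidx, drop = FALSE], c(1, 2), mean)
  corrected <- sweep(ispcmap$ispc, c(1, 2), base)
  # bootstrap null from baseline phase differences (extremes over K draws per
  # permutation, as in the power and ITPC masks)
  ntr <- ispcmap$n_trials; npf <- d[1] * d[2]; nb <- length(bidx)
  Db <- ispcmap$dphasor[, , , bidx, drop = FALSE]
  dim(Db) <- c(ntr, npf, nb)
  Db <- aperm(Db, c(1, 3, 2))
  idx <- null_draw_idx(nb, ntr, n_perm, seed)
  ext <- perm_null_minmax_mod(Db, c(ntr, nb, npf), idx, n_perm, nb)
  lo <- array(apply(sweep(ext$min, 2, as.numeric(base)), 2, quantile,
                    probs = alpha / 2, names = FALSE), d[1:2])
  hi <- array(apply(sweep(ext$max, 2, as.numeric(base)), 2, quantile,
                    probs = 1 - alpha / 2, names = FALSE), d[1:2])
  mask <- sweep(corrected, c(1, 2), hi, ">") | sweep(corrected, c(1, 2), lo, "<")
  corrected <- corrected * mask
  # volume-conduction exclusion per analysis window: per trial, the mean phase
  # difference over the window; v test over trials toward 0 and toward pi
  zcrit <- qnorm(1 - vtest_alpha)
  excluded <- array(FALSE, dim = c(d[1], d[2], length(windows)))
  for (w in seq_along(windows)) {
    widx <- time_indices(ispcmap$times, windows[[w]])
    Dw <- ispcmap$dphasor[, , , widx, drop = FALSE]
    dim(Dw) <- c(ntr * npf, length(widx))
    tm <- rowMeans(Dw)                       # per-trial window-mean phasor
    m <- Mod(tm)
    tm[m > 0] <- tm[m > 0] / m[m > 0]        # unit phasors (zeros dilute)
    dim(tm) <- c(ntr, npf)
    mean_ph <- colMeans(tm)
    V0 <- ntr * Re(mean_ph)                  # n*R*cos(theta - 0)
    Vpi <- -ntr * Re(mean_ph)                # n*R*cos(theta - pi)
    u0 <- V0 * sqrt(2 / ntr); upi <- Vpi * sqrt(2 / ntr)
    excluded[, , w] <- array(u0 > zcrit | upi > zcrit, d[1:2])
  }
  ispcmap$corrected <- corrected
  ispcmap$mask <- mask
  ispcmap$excluded <- excluded
  ispcmap$exclusion_windows <- windows
  ispcmap$boot <- list(n_perm = n_perm, alpha = alpha, vtest_alpha = vtest_alpha,
                       seed = seed, baseline_window = baseline)
  ispcmap$dphasor <- NULL  # no longer needed; large
  ispcmap
}

#' Connectivity degree per channel
#'
#' A pair counts as functionally connected when its mean masked,
#' baseline-corrected ISPC over the band (default 5-14 Hz) and window is
#' strictly positive, with volume-conduction-excluded pair/frequency entries
#' contributing 0. CD per channel is the connected-partner count normalized by
#' (channels - 1); regional means cover frontal (M2, M1), parietal (S1, PA,
#' RS) and occipital (V2, V1) electrodes.
#'
#' @param ispcmap a masked [ispc_significant()] result.
#' @param band frequency band in Hz.
#' @param window analysis window; must be one of the windows exclusions were
#'   computed for.
#' @return Object of class `connectivity_degree`: `cd` (per channel, in
#'   `[0, 1]`), `connected` (pair logical), `regional` (named means), `matrix`
#'   (square adjacency).
#' @export
connectivity_degree <- function(ispcmap, band = c(5, 14), window = c(0.18, 0.30)) {
  if (is.null(ispcmap$corrected)) stop("connectivity_degree needs a masked ISPC map")
  wmatch <- which(vapply(ispcmap$exclusion_windows, function(w)
    isTRUE(all.equal(w, window)), TRUE))
  if (length(wmatch) != 1)
    stop("window must match one of the exclusion windows used in ispc_significant()")
  fidx <- band_indices(ispcmap$freqs, band)
  tidx <- time_indices(ispcmap$times, window)
  np <- nrow(ispcmap$pairs)
  pair_mean <- numeric(np)
  for (p in seq_len(np)) {
    vals <- matrix(ispcmap$corrected[p, fidx, tidx], length(fidx))
    vals[ispcmap$excluded[p, fidx, wmatch], ] <- 0
    pair_mean[p] <- mean(vals)
  }
  connected <- pair_mean > 0
  nch <- length(ispcmap$channel_labels)
  adj <- matrix(0L, nch, nch, dimnames = list(ispcmap$channel_labels,
                                              ispcmap$channel_labels))
  for (p in which(connected)) {
    i <- ispcmap$pairs[p, 1]; j <- ispcmap$pairs[p, 2]
    adj[i, j] <- adj[j, i] <- 1L
  }
  cd <- rowSums(adj) / (nch - 1)
  names(cd) <- ispcmap$channel_labels
  regions <- region_of_label(ispcmap$channel_labels)
  regional <- vapply(c("frontal", "parietal", "occipital"),
                     function(r) if (any(regions %in% r)) mean(cd[regions %in% r]) else NA_real_,
                     0)
  structure(list(cd = cd, connected = connected, pair_mean = pair_mean,
                 matrix = adj, regional = regional, band = band,
                 window = window, cd_mean = mean(cd)),
            class = "connectivity_degree")
}

#' @export
print.connectivity_degree <- function(x, ...) {
  cat("<connectivity_degree> window ", x$window[1], "-", x$window[2], " s, band ",
      x$band[1], "-", x$band[2], " Hz: mean CD ", sprintf("%.3f", x$cd_mean),
      " (", sum(x$connected), " connected pairs)\n", sep = "")
  invisible(x)
}

#' Export a connectivity matrix as delimited text
#'
#' @param cd a [connectivity_degree()] result.
#' @param path output path (tab-separated square matrix with labels).
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(cd, path) {
  write.table(cd$matrix, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
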