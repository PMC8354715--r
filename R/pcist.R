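#' Parameters for the state-transition perturbational complexity index
#'
#' @param baseline baseline window in seconds (default -0.5 to -0.005).
#' @param response response window in seconds (default 0 to 0.6).
#' @param max_var cumulative variance (percent) the kept principal components
#'   must reach (default 99).
#' @param snr_min minimum component signal-to-noise ratio (default 1.8, the
#'   value at which surrogate complexity has median zero; see
#'   [calibrate_snr_min()]).
#' @param k baseline weighting of the state-transition contrast (default 1.2).
#' @param n_steps size of the threshold grid spanning the distance distribution
#'   (default 100).
#' @param n_surrogates surrogate pairs used for calibration (default 16).
#' @param clip_negative clip negative per-component transition contrasts at 0
#'   (default TRUE) so the index is nonnegative and the median-zero calibration
#'   is attainable.
#' @return list of class `pcist_params`.
#' @export
pcist_params <- function(baseline = c(-0.5, -0.005), response = c(0, 0.6),
                         max_var = 99, snr_min = 1.8, k = 1.2, n_steps = 100,
                         n_surrogates = 16, clip_negative = TRUE) {
  stopifnot(baseline[2] <= response[1] || response[2] <= baseline[1],
            max_var > 0, max_var <= 100, snr_min > 0)
  structure(list(baseline = baseline, response = response, max_var = max_var,
                 snr_min = snr_min, k = k, n_steps = n_steps,
                 n_surrogates = n_surrogates, clip_negative = clip_negative),
            class = "pcist_params")
}

#' Principal components of the evoked response with SNR gating
#'
#' Singular value decomposition of the trial-averaged response restricted to
#' the response window; the smallest leading set of spatial components reaching
#' `max_var` percent of the variance is kept, each component's full time course
#' is obtained by projection, and components whose response/baseline rms ratio
#' (SNR) falls below `snr_min` are dropped. Component signs are fixed so the
#' largest-magnitude channel loading is positive.
#'
#' @param erp channels x time matrix (trial-averaged response).
#' @param times time axis of `erp` in seconds.
#' @param params a [pcist_params()].
#' @return list with `timecourses` (kept components x time), `snr`,
#'   `singular_values`, `n_components` (after gating), `n_components_var`
#'   (before gating), `cum_var_pct`, `idx_response`, `idx_baseline`.
#' @export
reduce_components <- function(erp, times, params = pcist_params()) {
  idxR <- time_indices(times, params$response)
  idxB <- time_indices(times, params$baseline)
  X <- erp[, idxR, drop = FALSE]
  tot <- sum(X^2)
  if (tot == 0) {
    return(list(timecourses = matrix(0, 0, ncol(erp)), snr = numeric(0),
                singular_values = numeric(0), n_components = 0L,
                n_components_var = 0L, cum_var_pct = numeric(0),
                idx_response = idxR, idx_baseline = idxB))
  }
  sv <- svd(X)
  varpct <- cumsum(sv$d^2) / tot * 100
  ncv <- which(varpct >= params$max_var - 1e-9)[1]
  U <- sv$u[, seq_len(ncv), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncv)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  tc <- t(U) %*% erp   # components x full time
  snr <- vapply(seq_len(ncv), function(j)
    rms(tc[j, idxR]) / rms(tc[j, idxB]), 0)
  keep <- which(!is.nan(snr) & snr >= params$snr_min)  # Inf (silent baseline) passes
  list(timecourses = tc[keep, , drop = FALSE], snr = snr[keep],
       snr_all = snr, singular_values = sv$d[seq_len(ncv)],
       n_components = length(keep), n_components_var = ncv,
       cum_var_pct = varpct[seq_len(ncv)],
       idx_response = idxR, idx_baseline = idxB)
}

# Number of state transitions of a scalar time course segment at threshold eps:
# recurrence states R[i,t] = (|x_i - x_t| < eps), transitions counted along the
# time axis and normalized per time sample.
nst_at <- function(D, eps, n) {
  R <- D < eps
  sum(R[, -1, drop = FALSE] != R[, -n, drop = FALSE]) / n
}

#' Significant state transitions of one component time course
#'
#' Builds the pairwise absolute-difference (distance) matrix of the baseline
#' and response segments separately (embedding dimension 1); for each threshold
#' on a grid linearly spanning the pooled distance distribution, counts
#' recurrence-state transitions per time sample; the contrast is the maximum
#' over thresholds of NST_response - k * NST_baseline (clipped at 0 by
#' default).
#'
#' @param tc numeric component time course over the full epoch.
#' @param idx_baseline,idx_response sample indices of the two segments.
#' @param params a [pcist_params()].
#' @return scalar delta-NST.
#' @export
component_nst <- function(tc, idx_baseline, idx_response, params = pcist_params()) {
  xb <- tc[idx_baseline]; xr <- tc[idx_response]
  nb <- length(xb); nr <- length(xr)
  if (nb < 2 || nr < 2) stop("segments must have at least 2 samples")
  Db <- abs(outer(xb, xb, "-"))
  Dr <- abs(outer(xr, xr, "-"))
  dmax <- max(Db, Dr)
  if (dmax == 0) return(0)
  grid <- seq(dmax / params$n_steps, dmax, length.out = params$n_steps)
  dn <- vapply(grid, function(e) nst_at(Dr, e, nr) - params$k * nst_at(Db, e, nb), 0)
  out <- max(dn)
  if (params$clip_negative) max(out, 0) else out
}

#' State-transition perturbational complexity index (PCI-ST)
#'
#' The product of the number of principal components surviving dimensionality
#' reduction and SNR gating, and the mean significant state-transition contrast
#' across those components. High values require a response that is both
#' spatially differentiated (many independent components) and temporally
#' complex (many state transitions per component). The index is invariant to a
#' global amplitude rescaling and to channel permutations.
#'
#' @param erp channels x time matrix (trial-averaged response); an
#'   [eeg_epochs()] object is also accepted.
#' @param times time axis in seconds (taken from the epochs when `erp` is one).
#' @param params a [pcist_params()].
#' @return Object of class `pcist_result`: `value`, `n_components`,
#'   `delta_nst` (per component), `mean_nst`, `snr`, `params`.
#' @export
pcist <- function(erp, times = NULL, params = pcist_params()) {
  if (inherits(erp, "eeg_epochs")) {
    times <- erp$time_axis
    erp <- erp_mean(erp)
  }
  if (is.null(times)) times <- attr(erp, "times")
  if (is.null(times)) stop("times must be supplied")
  red <- reduce_components(erp, times, params)
  if (red$n_components == 0) {
    return(structure(list(value = 0, n_components = 0L, delta_nst = numeric(0),
                          mean_nst = 0, snr = numeric(0), params = params),
                     class = "pcist_result"))
  }
  dnst <- vapply(seq_len(red$n_components), function(j)
    component_nst(red$timecourses[j, ], red$idx_baseline, red$idx_response, params), 0)
  structure(list(value = red$n_components * mean(dnst),
                 n_components = red$n_components, delta_nst = dnst,
                 mean_nst = mean(dnst), snr = red$snr, params = params),
            class = "pcist_result")
}

#' @export
print.pcist_result <- function(x, ...) {
  cat("<pcist_result> PCI-ST = ", sprintf("%.2f", x$value), " (",
      x$n_components, " components, mean dNST ", sprintf("%.2f", x$mean_nst),
      ")\n", sep = "")
  invisible(x)
}

#' Calibrate the minimum component SNR on surrogate segments
#'
#' Draws `n_surrogates` pairs of non-overlapping random 0.5 s non-response
#' segments (t < 0 s or t > `post` s) from the trial-averaged signal, treats
#' one as baseline and one as response, and computes the surrogate PCI-ST for
#' every candidate SNR threshold (components and transition contrasts are
#' computed once per surrogate; the gate is swept). Returns the smallest
#' candidate for which the median surrogate PCI-ST is zero.
#'
#' @param epochs an [eeg_epochs()].
#' @param params a [pcist_params()].
#' @param candidate_grid ascending candidate SNR_min values (default 0.5 to 5
#'   by 0.1).
#' @param seg_len surrogate segment length in seconds (default 0.5).
#' @param post earliest post-response time considered non-response (default
#'   1.5 s).
#' @param seed RNG seed.
#' @return list with `snr_min`, `median_pcist` per candidate, `surrogates`
#'   (per-surrogate PCI-ST at the returned value), `candidate_grid`.
#' @export
calibrate_snr_min <- function(epochs, params = pcist_params(),
                              candidate_grid = seq(0.5, 5, by = 0.1),
                              seg_len = 0.5, post = 1.5, seed) {
  stopifnot(!is.unsorted(candidate_grid))
  erp <- erp_mean(epochs)
  times <- epochs$time_axis
  dt <- 1 / epochs$rate
  ok_start <- times[times + seg_len <= 0 |
                    (times >= post & times + seg_len <= times[length(times)] + dt)]
  ok_start <- ok_start[ok_start + seg_len <= times[length(times)] + dt / 2]
  if (length(ok_start) < 2) stop("epoch has less than 1 s of non-response signal")
  surr <- with_seed(seed, {
    lapply(seq_len(params$n_surrogates), function(s) {
      repeat {
        st <- sample(ok_start, 2)
        if (abs(st[1] - st[2]) >= seg_len) break
      }
      p2 <- params
      p2$baseline <- c(st[1], st[1] + seg_len)
      p2$response <- c(st[2], st[2] + seg_len)
      p2$snr_min <- 0   # gate swept afterwards
      red <- reduce_components(erp, times, p2)
      if (red$n_components == 0)
        return(list(snr = numeric(0), dnst = numeric(0)))
      dnst <- vapply(seq_len(red$n_components), function(j)
        component_nst(red$timecourses[j, ], red$idx_baseline, red$idx_response, p2), 0)
      list(snr = red$snr, dnst = dnst)
    })
  })
  med <- vapply(candidate_grid, function(cand) {
    vals <- vapply(surr, function(s) {
      keep <- s$snr >= cand
      if (!any(keep)) 0 else sum(keep) * mean(s$dnst[keep])
    }, 0)
    median(vals)
  }, 0)
  hit <- which(med == 0)
  if (length(hit) == 0)
    stop("no candidate SNR_min achieves median-zero surrogate complexity; grid: ",
         paste(candidate_grid, collapse = ", "))
  snr_min <- candidate_grid[hit[1]]
  vals <- vapply(surr, function(s) {
    keep <- s$snr >= snr_min
    if (!any(keep)) 0 else sum(keep) * mean(s$dnst[keep])
  }, 0)
  list(snr_min = snr_min, median_pcist = med, surrogates = vals,
       candidate_grid = candidate_grid, seed = seed)
}

#' PCI-ST time course over sliding windows
#'
#' PCI-ST computed in sliding response windows (default width 0.1 s, shift
#' 0.02 s, from stimulus onset until 1.1 s -> 51 windows) sharing the standard
#' baseline, plus the fixed-window value for 0.08-0.6 s. Components are
#' re-derived per window.
#'
#' @param erp channels x time matrix or [eeg_epochs()].
#' @param times time axis (unless `erp` is an epochs object).
#' @param params a [pcist_params()].
#' @param width,shift,until sliding-window geometry in seconds.
#' @return Object of class `pcist_timecourse`: `starts`, `values`,
#'   `fixed_value` (0.08-0.6 s), `width`.
#' @export
pcist_timecourse <- function(erp, times = NULL, params = pcist_params(),
                             width = 0.1, shift = 0.02, until = 1.1) {
  if (width > until) stop("window width exceeds the analysis range")
  if (inherits(erp, "eeg_epochs")) {
    times <- erp$time_axis
    erp <- erp_mean(erp)
  }
  starts <- seq(0, until - width, by = shift)
  values <- vapply(starts, function(s) {
    p <- params; p$response <- c(s, s + width)
    pcist(erp, times, p)$value
  }, 0)
  pfix <- params; pfix$response <- c(0.08, 0.6)
  structure(list(starts = starts, values = values, width = width,
                 fixed_value = pcist(erp, times, pfix)$value),
            class = "pcist_timecourse")
}

#' @export
print.pcist_timecourse <- function(x, ...) {
  cat("<pcist_timecourse> ", length(x$starts), " windows of ", x$width,
      " s; max ", sprintf("%.2f", max(x$values)), " at ",
      sprintf("%.2f", x$starts[which.max(x$values)]), " s; fixed 0.08-0.6 s: ",
      sprintf("%.2f", x$fixed_value), "\n", sep = "")
  invisible(x)
}
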