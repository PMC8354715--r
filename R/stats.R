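#' Exact two-tailed Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (with a flag), absolute differences are
#' mid-ranked, and for n <= 25 the exact permutation distribution of the
#' positive-rank sum over all 2^n sign assignments is computed by dynamic
#' programming (ranks doubled so mid-ranks stay integral); beyond that a normal
#' approximation with tie correction and continuity correction is used. For
#' n = 9 pairs all of one sign this yields p = 2/512 = 0.00390625.
#'
#' @param a,b paired condition values (equal length), or `b = NULL` and `a` the
#'   differences.
#' @return list with `p`, `statistic` (positive-rank sum W+), `n` (non-zero
#'   pairs), `method`, `all_zero` flag.
#' @export
wilcoxon_exact <- function(a, b = NULL) {
  d <- if (is.null(b)) a else b - a
  if (length(d) < 2) stop("need at least 2 pairs")
  if (anyNA(d)) stop("missing pairs are not allowed")
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(p = 1, statistic = NA_real_, n = 0L, method = "degenerate",
                all_zero = TRUE))
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))       # doubled mid-ranks are integers
    tot <- sum(r2)
    counts <- numeric(tot + 1)           # counts[s + 1] = #assignments with 2W = s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(tot + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p = p, statistic = w, n = n, method = method, all_zero = FALSE)
}

#' Mean difference with BCa bootstrap confidence interval
#'
#' Estimation statistics for a paired contrast: the mean of the paired
#' differences with a bias-corrected and accelerated bootstrap interval
#' (default 5000 resamples, 95% CI), reproducible under a fixed seed.
#'
#' @param a,b paired condition values; the effect is `mean(b - a)`.
#' @param n_resamples bootstrap resamples (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with `mean_diff`, `ci` (lower, upper), `n_resamples`, `seed`.
#' @export
bca_mean_diff <- function(a, b, n_resamples = 5000, conf = 0.95, seed) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  if (sd(d) == 0)
    return(list(mean_diff = mean(d), ci = c(mean(d), mean(d)),
                n_resamples = n_resamples, seed = seed))
  bt <- with_seed(seed,
    boot::boot(d, statistic = function(x, i) mean(x[i]), R = n_resamples))
  ci <- boot::boot.ci(bt, conf = conf, type = "bca")
  list(mean_diff = mean(d), ci = ci$bca[1, 4:5],
       n_resamples = n_resamples, seed = seed)
}

#' Weighted least-squares linear fit
#'
#' Slope and intercept by weighted least squares (weights typically inverse
#' squared error bars when fitting averages), with the coefficient of
#' determination and a t test of slope = 0.
#'
#' @param x,y data vectors (>= 3 points).
#' @param weights observation weights (default: uniform, i.e. ordinary least
#'   squares).
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
weighted_linfit <- function(x, y, weights = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2) stop("degenerate x: all values identical")
  if (is.null(weights)) weights <- rep(1, length(x))
  fit <- lm(y ~ x, weights = weights)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p = unname(s$coefficients[2, 4]))
}

#' Mann-Whitney (rank-sum) test for two independent groups
#'
#' Two-tailed; exact when group sizes permit and there are no ties.
#'
#' @param u1,u2 group values.
#' @return list with `p`, `statistic`.
#' @export
mann_whitney <- function(u1, u2) {
  if (length(u1) < 1 || length(u2) < 1) stop("both groups need observations")
  w <- suppressWarnings(wilcox.test(u1, u2))
  list(p = w$p.value, statistic = unname(w$statistic))
}

#' Friedman test for a repeated-measures design
#'
#' @param mat blocks x treatments matrix (rows: rats/sessions).
#' @return list with `p`, `statistic`, `df`.
#' @export
friedman <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 treatments")
  f <- friedman.test(mat)
  stat <- unname(f$statistic); p <- f$p.value
  if (is.nan(stat)) {  # fully tied blocks: no treatment effect by construction
    stat <- 0; p <- 1
  }
  list(p = p, statistic = stat, df = unname(f$parameter))
}
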