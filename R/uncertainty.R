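#' Decorrelation scale from the autocorrelation e-folding
#'
#' Lag (in units of the sample spacing times `spacing`) at which the sample
#' autocorrelation of a demeaned series first drops below 1/e, linearly
#' interpolated between the bracketing integer lags. Serially correlated
#' geophysical records carry fewer independent samples than raw samples;
#' this scale feeds [effective_n()].
#'
#' When the autocorrelation never crosses 1/e within half the record the
#' scale is set to half the record length and flagged (`crossed = FALSE`).
#'
#' @param x numeric series (regularly spaced)
#' @param spacing sample spacing in physical units (e.g. days); default 1
#' @return list with `scale` (physical units), `crossed` (logical flag)
#' @export
efold_decorrelation <- function(x, spacing = 1) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("need at least 20 samples to estimate a decorrelation scale")
  if (stats::sd(x) == 0) return(list(scale = NA_real_, crossed = FALSE))
  max_lag <- floor(n / 2)
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  thr <- exp(-1)
  below <- which(r < thr)
  if (length(below) == 0) {
    return(list(scale = max_lag * spacing, crossed = FALSE))
  }
  k <- below[1] - 1            # lag index (r[1] is lag 0)
  if (k == 0) return(list(scale = spacing, crossed = TRUE))
  # interpolate between lag k-1 (r >= 1/e) and lag k (r < 1/e)
  r_hi <- r[k]; r_lo <- r[k + 1]
  frac <- (r_hi - thr) / (r_hi - r_lo)
  list(scale = (k - 1 + frac) * spacing, crossed = TRUE)
}

#' Effective number of independent samples
#'
#' Record length divided by the decorrelation scale, floored at 2 and capped
#' at the raw sample count. Example: 100 days of daily data with a 10-day
#' decorrelation scale carry 10 independent samples.
#'
#' @param n_raw number of raw samples
#' @param scale decorrelation scale in units of `spacing`
#' @param spacing sample spacing (same units as `scale`); default 1
#' @return effective sample size (numeric, >= 2)
#' @export
effective_n <- function(n_raw, scale, spacing = 1) {
  if (!is.finite(scale) || scale <= 0) stop("decorrelation scale must be > 0")
  n_eff <- n_raw * spacing / max(scale, spacing)
  max(2, min(n_raw, n_eff))
}

#' Standard error and 95 % confidence limits
#'
#' `standard_error()` computes SE = sd/sqrt(n_eff) with `n_eff` the number of
#' independent samples; `cl95()` converts to two-sided 95 % limits
#' mean +/- 1.96 SE.
#'
#' @param x sample values
#' @param n_effective effective number of independent samples (defaults to
#'   the number of finite values, i.e. the iid case)
#' @return `standard_error`: numeric SE. `cl95`: numeric length-2 vector
#'   `c(lower, upper)`.
#' @export
standard_error <- function(x, n_effective = NULL) {
  x <- x[is.finite(x)]
  if (is.null(n_effective)) n_effective <- length(x)
  if (n_effective < 2) stop("n_effective must be >= 2")
  stats::sd(x) / sqrt(n_effective)
}

#' @rdname standard_error
#' @param mean_x the mean the limits are centred on
#' @param se its standard error
#' @export
cl95 <- function(mean_x, se) {
  c(lower = mean_x - 1.96 * se, upper = mean_x + 1.96 * se)
}

#' Error propagation for a difference
#'
#' SE of a difference of two independent quantities:
#' sqrt(SE_a^2 + SE_b^2). Independence is assumed (the two series behind the
#' difference are measured by distinct instruments).
#'
#' @param se_a,se_b standard errors of the two terms
#' @return propagated SE
#' @export
propagate_difference <- function(se_a, se_b) {
  sqrt(se_a^2 + se_b^2)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' 2.5/97.5 percentile bootstrap of the sample mean, deterministic for a
#' given seed. Used for dissipation-rate depth-bin averages, whose strongly
#' skewed (near-lognormal) distributions make SE-based limits unreliable.
#'
#' @param x sample values (>= 5 finite values required)
#' @param reps bootstrap replicates (default 2000)
#' @param seed RNG seed (optional; NULL uses the current RNG stream)
#' @return length-2 vector `c(lower, upper)`
#' @export
bootstrap_mean_ci <- function(x, reps = 2000, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("need at least 5 values for a bootstrap CI")
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = reps)
    rowMeans(matrix(x[idx], nrow = reps))
  })
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Pearson correlation on paired finite entries
#'
#' @param x,y numeric vectors of equal length; pairs with any non-finite
#'   entry are dropped
#' @return product-moment correlation coefficient
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  stats::cor(x[ok], y[ok])
}
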