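# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic generators in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

stopifnot_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!all(is.finite(args[[i]]))) {
      stop("non-finite value in '", nm[i], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Modified Akima (makima) interpolation
#'
#' C1 piecewise-cubic Hermite interpolation whose node slopes use the
#' modified Akima weighting
#' \deqn{s_i = (w_1 \delta_{i-1} + w_2 \delta_i)/(w_1 + w_2)}
#' with \eqn{w_1 = |\delta_{i+1} - \delta_i| + |\delta_{i+1} + \delta_i|/2}
#' and \eqn{w_2 = |\delta_{i-1} - \delta_{i-2}| + |\delta_{i-1} +
#' \delta_{i-2}|/2}, where \eqn{\delta_i} are the secant slopes. The added
#' averaged-magnitude term (the "modification" relative to classic Akima)
#' suppresses overshoot next to flat regions, which is why it is the standard
#' choice for regridding oceanographic profiles onto fine vertical or
#' isopycnal grids.
#'
#' @param x strictly increasing abscissa of the data
#' @param y data values
#' @param xout points at which to evaluate the interpolant
#' @param extrapolate if `FALSE` (default) points outside `range(x)` return
#'   `NA` rather than an extrapolated value
#' @return numeric vector of interpolated values at `xout`
#' @export
interp_makima <- function(x, y, xout, extrapolate = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(rep(NA_real_, length(xout)))
  if (is.unsorted(x, strictly = TRUE)) {
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (anyDuplicated(x)) stop("duplicated abscissa values")
  }
  if (n == 2) {
    out <- y[1] + (xout - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  } else {
    d <- diff(y) / diff(x)
    # pad secant slopes by quadratic extrapolation (Akima's rule)
    dpad <- c(2 * d[1] - d[2], d, 2 * d[n - 1] - d[n - 2])
    dpad <- c(2 * dpad[1] - dpad[2], dpad, 2 * dpad[n + 1] - dpad[n])
    # dpad[i + 2] is delta_i for i = 0..n; node i uses delta_{i-2..i+1}
    s <- numeric(n)
    for (i in seq_len(n)) {
      dm2 <- dpad[i]; dm1 <- dpad[i + 1]; dp0 <- dpad[i + 2]; dp1 <- dpad[i + 3]
      w1 <- abs(dp1 - dp0) + abs(dp1 + dp0) / 2
      w2 <- abs(dm1 - dm2) + abs(dm1 + dm2) / 2
      s[i] <- if (w1 + w2 == 0) 0 else (w1 * dm1 + w2 * dp0) / (w1 + w2)
    }
    out <- stats::splinefunH(x, y, m = s)(xout)
  }
  if (!extrapolate) out[xout < x[1] | xout > x[n]] <- NA_real_
  out
}

# slope of the least-squares line of y on x (equals the centred difference
# for symmetric windows on linear data); NA when fewer than `min_n` points
ls_slope <- function(x, y, min_n = 3) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(NA_real_)
  sum(xc * (y - mean(y))) / denom
}

# day-of-year folding (leap day -> 365), vectorised
fold_doy <- function(doy) {
  d <- ((doy - 1) %% 365) + 1
  d
}

# circular day-of-year distance on a 365-day year
circ_doy_dist <- function(a, b) {
  d <- abs(a - b) %% 365
  pmin(d, 365 - d)
}
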