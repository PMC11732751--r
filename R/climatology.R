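#' Seasonal climatology container
#'
#' A phase grid (day-of-year), composite values, standard errors and
#' effective sample sizes. Built by the mooring, Argo-style and monthly
#' climatology estimators.
#'
#' @param phase day-of-year grid
#' @param value composite values
#' @param se standard errors (>= 0)
#' @param n_effective effective independent samples per entry
#' @return object of class `seasonal_climatology` (a data.frame)
#' @export
seasonal_climatology <- function(phase, value, se, n_effective) {
  stopifnot(all(phase >= 1 & phase <= 365),
            all(se >= 0 | is.na(se)))
  structure(data.frame(phase = phase, value = value, se = se,
                       n_effective = n_effective),
            class = c("seasonal_climatology", "data.frame"))
}

#' @export
print.seasonal_climatology <- function(x, ...) {
  cat(sprintf("<seasonal_climatology> %d entries, value %.3g to %.3g\n",
              nrow(x), min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  NextMethod()
}

#' @export
plot.seasonal_climatology <- function(x, ylab = "value", ...) {
  graphics::plot(x$phase, x$value, type = "l", xlab = "day of year",
                 ylab = ylab, ...)
  graphics::arrows(x$phase, x$value - x$se, x$phase, x$value + x$se,
                   angle = 90, code = 3, length = 0.02, col = "grey40")
  invisible(x)
}

#' Default 15-day phase grid
#'
#' 25 entries every 15 days, 1:15:361, covering the 365-day year.
#' @return numeric vector of day-of-year values
#' @export
phase_grid_15d <- function() seq(1, 361, by = 15)

#' Seasonal composite of a mooring series
#'
#' Composite mean over all years per phase bin (15-day bins on the default
#' grid), with standard errors based on the effective number of independent
#' samples: per bin, the contributing record length divided by the series'
#' decorrelation timescale (estimated from the full demeaned-of-season
#' series via the autocorrelation e-folding unless supplied).
#'
#' @param time sample times, days from record start (regular cadence)
#' @param value sample values
#' @param phase_grid day-of-year grid (default [phase_grid_15d()])
#' @param half_window bin half-width, days (default half the grid spacing)
#' @param scale decorrelation timescale, days; estimated when NULL
#' @param cadence sample spacing, days
#' @return a [seasonal_climatology()]
#' @export
mooring_seasonal_cycle <- function(time, value, phase_grid = phase_grid_15d(),
                                   half_window = NULL, scale = NULL,
                                   cadence = 1) {
  ok <- is.finite(value)
  time <- time[ok]; value <- value[ok]
  if ((max(time) - min(time)) < 365) stop("need at least one year of data")
  if (is.null(half_window)) {
    half_window <- if (length(phase_grid) > 1) diff(phase_grid)[1] / 2 else 7.5
  }
  doy <- fold_doy(time + 1)
  if (is.null(scale)) {
    # decorrelation of the anomaly about a first-pass seasonal fit, so the
    # seasonal cycle itself does not inflate the timescale
    X <- cbind(1, cos(2 * pi * doy / 365), sin(2 * pi * doy / 365),
               cos(4 * pi * doy / 365), sin(4 * pi * doy / 365))
    anom <- stats::residuals(stats::lm.fit(X, value))
    dec <- efold_decorrelation(anom, spacing = cadence)
    scale <- if (is.finite(dec$scale)) dec$scale else cadence
  }
  val <- se <- neff <- rep(NA_real_, length(phase_grid))
  for (i in seq_along(phase_grid)) {
    sel <- circ_doy_dist(doy, phase_grid[i]) <= half_window
    if (!any(sel)) next
    v <- value[sel]
    val[i] <- mean(v)
    neff[i] <- effective_n(length(v), scale, spacing = cadence)
    se[i] <- standard_error(v, neff[i])
  }
  seasonal_climatology(phase_grid, val, se, neff)
}

#' Seasonal cycle of the core--isotherm depth difference
#'
#' The seasonal cycles of the two depth series are computed individually
#' and then differenced; the standard error of the difference follows from
#' error propagation, SE = sqrt(SE_euc^2 + SE_20^2) (the two series come
#' from independent instruments).
#'
#' @param clim_euc,clim_20 `seasonal_climatology` objects of D_EUC and
#'   D_20C on the same phase grid
#' @return a [seasonal_climatology()] of D_EUC - D_20C
#' @export
depth_difference_cycle <- function(clim_euc, clim_20) {
  if (!isTRUE(all.equal(clim_euc$phase, clim_20$phase))) {
    stop("phase grids differ")
  }
  seasonal_climatology(clim_euc$phase,
                       clim_euc$value - clim_20$value,
                       propagate_difference(clim_euc$se, clim_20$se),
                       pmin(clim_euc$n_effective, clim_20$n_effective))
}

#' Gaussian-distance-weighted seasonal climatology from a profile cloud
#'
#' Argo-style three-step climatology at a site:
#' \enumerate{
#'   \item select profiles inside an ellipse (default 8 degrees longitude
#'     radius, 3 degrees latitude) and within +/- 45 days of each 15-day
#'     phase entry (circular in day-of-year);
#'   \item remove outliers outside 1.5 IQR beyond the first/third quartile
#'     of the selected values;
#'   \item weighted least squares of value on [1, dlon, dlat, dlat^2]
#'     (predictors centred on the site) with Gaussian distance weights
#'     exp(-d^2 / (2 L^2)), L = 200 km, d the great-circle distance to the
#'     site. The climatology value is the intercept (the site prediction)
#'     and its SE the weighted-regression standard error of the intercept.
#' }
#'
#' @param cloud data.frame with `lon`, `lat`, `doy`, `value` (as produced
#'   by [make_argo_cloud()]`$data`)
#' @param site c(lon, lat), degrees
#' @param ellipse c(lon_radius, lat_radius), degrees
#' @param phase_grid day-of-year grid (default [phase_grid_15d()])
#' @param half_window selection half-window, days
#' @param L Gaussian weighting decorrelation scale, km; `Inf` gives
#'   ordinary least squares
#' @param iqr_k IQR multiplier of the outlier filter
#' @param min_profiles minimum profiles per entry after filtering
#' @return a [seasonal_climatology()]
#' @export
argo_climatology <- function(cloud, site, ellipse = c(8, 3),
                             phase_grid = phase_grid_15d(),
                             half_window = 45, L = 200, iqr_k = 1.5,
                             min_profiles = 10) {
  dlon <- cloud$lon - site[1]
  dlat <- cloud$lat - site[2]
  in_ell <- (dlon / ellipse[1])^2 + (dlat / ellipse[2])^2 <= 1
  d_km <- geosphere::distHaversine(cbind(cloud$lon, cloud$lat),
                                   site) / 1000
  w_all <- if (is.infinite(L)) rep(1, nrow(cloud)) else exp(-d_km^2 / (2 * L^2))
  val <- se <- neff <- rep(NA_real_, length(phase_grid))
  for (i in seq_along(phase_grid)) {
    sel <- in_ell & circ_doy_dist(cloud$doy, phase_grid[i]) <= half_window
    if (sum(sel) < min_profiles) next
    v <- cloud$value[sel]
    keep <- iqr_keep(v, iqr_k)
    if (sum(keep) < min_profiles) next
    X <- cbind(1, dlon[sel][keep], dlat[sel][keep], dlat[sel][keep]^2)
    w <- w_all[sel][keep]
    # weighted least squares with the standard lm covariance:
    # vcov = s^2 (X'WX)^-1, s^2 = sum(w r^2)/(n - p)
    xtwx <- crossprod(X * sqrt(w))
    if (qr(xtwx)$rank < ncol(X)) next            # rank-deficient design
    beta <- solve(xtwx, crossprod(X * w, v[keep]))
    r <- v[keep] - X %*% beta
    s2 <- sum(w * r^2) / (length(w) - ncol(X))
    val[i] <- beta[1]
    se[i] <- sqrt(s2 * solve(xtwx)[1, 1])
    neff[i] <- sum(keep)
  }
  seasonal_climatology(phase_grid, val, se, neff)
}

# interquartile-range outlier filter: keep values within k*IQR of the
# first/third quartile
iqr_keep <- function(v, k = 1.5) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  v >= q[1] - k * iqr & v <= q[2] + k * iqr
}

#' Richardson-number seasonal climatology
#'
#' Elementwise ratio of the N^2 climatology to the Sh^2 climatology --
#' explicitly the ratio of climatologies, not the climatology of
#' instantaneous ratios (the two differ whenever N^2 and Sh^2 fluctuations
#' are correlated). SEs are propagated in the small-relative-error
#' approximation.
#'
#' @param clim_n2,clim_sh2 `seasonal_climatology` objects on the same grid
#' @return a `seasonal_climatology` of Ri with an `unstable` column
#'   (Ri < 0.25)
#' @export
ri_climatology <- function(clim_n2, clim_sh2) {
  if (!isTRUE(all.equal(clim_n2$phase, clim_sh2$phase))) {
    stop("phase grids differ")
  }
  ri <- clim_n2$value / clim_sh2$value
  ri[is.finite(clim_sh2$value) & clim_sh2$value == 0] <- NA_real_
  se <- abs(ri) * sqrt((clim_n2$se / clim_n2$value)^2 +
                         (clim_sh2$se / clim_sh2$value)^2)
  out <- seasonal_climatology(clim_n2$phase, ri, se,
                              pmin(clim_n2$n_effective,
                                   clim_sh2$n_effective))
  out$unstable <- is.finite(ri) & ri < 0.25
  out
}

# first day-of-year of each calendar month (non-leap year)
.month_start <- cumsum(c(1, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))

doy_to_month <- function(doy) {
  findInterval(fold_doy(doy), .month_start)
}

#' Monthly dissipation climatology from moored records
#'
#' Monthly composite mean of a moored dissipation series per depth cell,
#' with percentile-bootstrap 95 % confidence limits (dissipation samples
#' are strongly skewed, so SE-based limits would be unreliable).
#'
#' @param time sample times, days
#' @param epsilon dissipation samples, W/kg
#' @param depth depth-cell label per sample (optional; single cell when
#'   missing)
#' @param reps bootstrap replicates
#' @param seed RNG seed for the bootstrap
#' @return data.frame with `month`, `depth`, `epsilon`, `lower`, `upper`,
#'   `n`
#' @export
monthly_epsilon_climatology <- function(time, epsilon, depth = NULL,
                                        reps = 2000, seed = NULL) {
  if (is.null(depth)) depth <- rep(0, length(time))
  ok <- is.finite(epsilon)
  month <- doy_to_month(fold_doy(time[ok] + 1))
  epsilon <- epsilon[ok]; depth <- depth[ok]
  grid <- expand.grid(month = 1:12, depth = sort(unique(depth)))
  grid$epsilon <- grid$lower <- grid$upper <- NA_real_
  grid$n <- 0L
  for (r in seq_len(nrow(grid))) {
    v <- epsilon[month == grid$month[r] & depth == grid$depth[r]]
    if (length(v) == 0) next
    grid$epsilon[r] <- mean(v)
    grid$n[r] <- length(v)
    if (length(v) >= 5) {
      ci <- bootstrap_mean_ci(v, reps = reps, seed = seed)
      grid$lower[r] <- ci[1]; grid$upper[r] <- ci[2]
    }
  }
  grid
}
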