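#' Velocity field container
#'
#' Zonal and meridional velocity on a depth-by-axis grid, where the second
#' axis is either station longitude (shipboard section) or time in days
#' (moored record). Eastward u is positive; depth is positive down.
#'
#' @param depth depth axis, m, strictly increasing
#' @param axis station longitudes (degrees) or times (days)
#' @param u,v velocity matrices, m/s, dim `c(length(depth), length(axis))`;
#'   `v` defaults to zero (meridional shear is small at the equator)
#' @param provenance "shipboard" or "moored"
#' @return an object of class `velocity_field`
#' @export
velocity_field <- function(depth, axis, u, v = NULL,
                           provenance = c("shipboard", "moored")) {
  provenance <- match.arg(provenance)
  u <- as.matrix(u)
  if (is.null(v)) v <- matrix(0, nrow(u), ncol(u))
  v <- as.matrix(v)
  if (is.unsorted(depth, strictly = TRUE)) stop("depth must be increasing")
  if (!all(dim(u) == c(length(depth), length(axis))) ||
      !all(dim(v) == dim(u))) {
    stop("u, v must be depth x axis matrices")
  }
  if (max(abs(u), na.rm = TRUE) >= 3 || max(abs(v), na.rm = TRUE) >= 3) {
    stop("|u|, |v| must be < 3 m/s")
  }
  structure(list(depth = as.numeric(depth), axis = as.numeric(axis),
                 u = u, v = v, provenance = provenance),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %s, %d depths x %d columns, u in [%.2f, %.2f] m/s\n",
              x$provenance, length(x$depth), length(x$axis),
              min(x$u, na.rm = TRUE), max(x$u, na.rm = TRUE)))
  invisible(x)
}

#' Equatorial Undercurrent core detection
#'
#' Finds the depth of maximum eastward velocity between `z_range[1]` and
#' `z_range[2]` (default 20--150 m), then refines it by a least-squares
#' second-degree polynomial fitted to the velocity samples within a
#' `2*half_window` (default 32 m) depth range centred on the discrete
#' maximum. The core depth is the vertex of the parabola and the core speed
#' the fitted velocity there. Degenerate fits (upward-opening parabola, or
#' vertex outside the fit window) fall back to the discrete maximum and are
#' flagged. Ties in the discrete maximum resolve to the shallowest depth.
#'
#' @param depth depth axis, m
#' @param u eastward velocity profile, m/s
#' @param z_range search range, m
#' @param half_window half-width of the quadratic fit window, m
#' @return object of class `euc_core`: list with `depth` (m), `speed` (m/s),
#'   `flag` ("ok", "fallback_discrete", "no_euc", "too_few_samples"),
#'   `window` (fit window used)
#' @export
euc_core <- function(depth, u, z_range = c(20, 150), half_window = 16) {
  ok <- is.finite(u) & depth >= z_range[1] & depth <= z_range[2]
  out <- structure(list(depth = NA_real_, speed = NA_real_,
                        flag = "no_euc", window = c(NA_real_, NA_real_)),
                   class = "euc_core")
  if (!any(ok)) return(out)
  z <- depth[ok]; uu <- u[ok]
  imax <- which.max(uu)              # which.max takes the first (shallowest) tie
  if (uu[imax] <= 0) return(out)
  zmax <- z[imax]
  win <- ok & abs(depth - zmax) <= half_window
  zw <- depth[win]; uw <- u[win]
  out$window <- c(zmax - half_window, zmax + half_window)
  if (length(zw) < 3) {
    out$depth <- zmax; out$speed <- uu[imax]; out$flag <- "too_few_samples"
    return(out)
  }
  zc <- zw - zmax                    # centre for conditioning
  fit <- unname(stats::lm.fit(cbind(1, zc, zc^2), uw)$coefficients)
  a <- fit[1]; b <- fit[2]; cc <- fit[3]
  if (!is.finite(cc) || cc >= 0) {
    out$depth <- zmax; out$speed <- uu[imax]; out$flag <- "fallback_discrete"
    return(out)
  }
  vz <- -b / (2 * cc)
  if (abs(vz) > half_window) {
    out$depth <- zmax; out$speed <- uu[imax]; out$flag <- "fallback_discrete"
    return(out)
  }
  out$depth <- unname(zmax + vz)
  out$speed <- unname(a + b * vz + cc * vz^2)
  out$flag <- "ok"
  out
}

#' @export
print.euc_core <- function(x, ...) {
  if (is.na(x$depth)) {
    cat("<euc_core> undefined (", x$flag, ")\n", sep = "")
  } else {
    cat(sprintf("<euc_core> depth %.1f m, speed %.2f m/s [%s]\n",
                x$depth, x$speed, x$flag))
  }
  invisible(x)
}

#' EUC core at a station time
#'
#' Averages the eastward velocity profiles of a moored or underway record
#' within `half_window` (default 2 h = 1/12 day) of a station timestamp,
#' then detects the core with [euc_core()].
#'
#' @param field a `velocity_field` whose axis is time in days
#' @param station_time time of the station, days
#' @param half_window averaging half-window, days
#' @param ... passed to [euc_core()]
#' @return an `euc_core` (flag "no_data" when no profiles fall in the window)
#' @export
euc_core_at_station <- function(field, station_time, half_window = 2 / 24,
                                ...) {
  sel <- abs(field$axis - station_time) <= half_window
  if (!any(sel)) {
    return(structure(list(depth = NA_real_, speed = NA_real_,
                          flag = "no_data", window = c(NA_real_, NA_real_)),
                     class = "euc_core"))
  }
  u_mean <- rowMeans(field$u[, sel, drop = FALSE], na.rm = TRUE)
  euc_core(field$depth, u_mean, ...)
}

#' Squared vertical shear of horizontal velocity
#'
#' Regrids u and v onto a 1-m depth grid (modified-Akima interpolation),
#' masks the upper `mask_upper` metres (default 20 m, where shipboard/moored
#' ADCP data are unreliable), computes the vertical derivatives as the
#' least-squares slope over a running window (default 10 m, equal to the
#' centred difference for linear data), and returns
#' Sh^2 = u_z^2 + v_z^2 on the 1-m grid.
#'
#' @param field a `velocity_field`
#' @param grid target depth grid, m (default 0:200)
#' @param window running window for the derivative, m
#' @param mask_upper depth above which velocities are discarded, m
#' @return list with `depth`, `axis`, `sh2` (matrix), `u_z`, `v_z`
#' @export
shear_squared <- function(field, grid = 0:200, window = 10, mask_upper = 20) {
  nz <- length(grid)
  na_col <- length(field$axis)
  regrid <- function(m) {
    out <- matrix(NA_real_, nz, na_col)
    for (j in seq_len(na_col)) {
      out[, j] <- interp_makima(field$depth, m[, j], grid)
    }
    out[grid < mask_upper, ] <- NA_real_
    out
  }
  ug <- regrid(field$u)
  vg <- regrid(field$v)
  half <- window / 2
  deriv <- function(m) {
    out <- matrix(NA_real_, nz, na_col)
    for (j in seq_len(na_col)) {
      col <- m[, j]
      for (i in seq_len(nz)) {
        sel <- abs(grid - grid[i]) <= half
        # window must be complete: full span and all samples valid
        if (grid[i] - half < grid[1] || grid[i] + half > grid[nz]) next
        if (any(!is.finite(col[sel]))) next
        out[i, j] <- ls_slope(grid[sel], col[sel])
      }
    }
    out
  }
  u_z <- deriv(ug)
  v_z <- deriv(vg)
  list(depth = grid, axis = field$axis, sh2 = u_z^2 + v_z^2,
       u_z = u_z, v_z = v_z, u = ug, v = vg)
}

#' Richardson number
#'
#' Elementwise Ri = N^2 / Sh^2. Vanishing shear yields an undefined entry
#' (not infinity); negative N^2 yields a negative Ri, flagged unstable in
#' the returned mask. `unstable` marks Ri < 0.25, the canonical threshold
#' for growing shear instabilities.
#'
#' @param n2 squared buoyancy frequency, 1/s^2 (vector or matrix)
#' @param sh2 squared shear, 1/s^2, same shape
#' @return list with `ri`, `unstable` (logical, Ri < 0.25)
#' @export
richardson <- function(n2, sh2) {
  if (!all(dim(as.matrix(n2)) == dim(as.matrix(sh2)))) {
    stop("N^2 and Sh^2 grids do not match")
  }
  ri <- n2 / sh2
  ri[is.finite(sh2) & sh2 == 0] <- NA_real_
  list(ri = ri, unstable = is.finite(ri) & ri < 0.25)
}

#' Ten-day block means
#'
#' Non-overlapping 10-day block means of a daily series or of each row of a
#' depth-by-time field. Blocks with less than `min_frac` valid data are
#' undefined.
#'
#' @param x numeric vector (daily) or matrix (rows = depth, cols = days)
#' @param block block length in samples (default 10)
#' @param min_frac minimum fraction of valid samples per block
#' @return vector or matrix of block means
#' @export
ten_day_mean <- function(x, block = 10, min_frac = 0.5) {
  blockmean <- function(v) {
    nb <- floor(length(v) / block)
    v <- v[seq_len(nb * block)]
    m <- matrix(v, nrow = block)
    out <- colMeans(m, na.rm = TRUE)
    out[colMeans(is.finite(m)) < min_frac] <- NA_real_
    out
  }
  if (is.matrix(x)) t(apply(x, 1, blockmean)) else blockmean(x)
}
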