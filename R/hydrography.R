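#' Hydrographic profile container
#'
#' A single vertical cast of conservative temperature, absolute salinity and
#' (optionally) nitrate on a strictly increasing depth axis (m, positive
#' down). Pressure (dbar) may be supplied instead of depth and is converted
#' hydrostatically at the profile latitude. Potential density anomaly
#' sigma-theta is derived on construction.
#'
#' @param depth depth axis, m positive down (give either this or `pressure`)
#' @param pressure pressure axis, dbar
#' @param temperature conservative temperature, degC
#' @param salinity absolute salinity, g/kg
#' @param nitrate nitrate concentration, umol/kg (optional)
#' @param lon,lat position, degrees
#' @param time observation time: day-of-year (numeric) or anything coercible
#' @return an object of class `ocean_profile`
#' @export
ocean_profile <- function(depth = NULL, pressure = NULL, temperature,
                          salinity, nitrate = NULL, lon = NA_real_,
                          lat = 0, time = NA_real_) {
  if (is.null(depth) && is.null(pressure)) {
    stop("supply either 'depth' or 'pressure'")
  }
  if (is.null(depth)) depth <- pressure_to_depth(pressure, lat)
  if (is.null(pressure)) pressure <- depth_to_pressure(depth, lat)
  n <- length(depth)
  if (is.unsorted(depth, strictly = TRUE)) {
    stop("depth axis must be strictly increasing")
  }
  if (length(temperature) != n || length(salinity) != n) {
    stop("temperature/salinity length must match the depth axis")
  }
  if (!is.null(nitrate) && length(nitrate) != n) {
    stop("nitrate length must match the depth axis")
  }
  structure(list(
    depth = as.numeric(depth), pressure = as.numeric(pressure),
    temperature = as.numeric(temperature), salinity = as.numeric(salinity),
    nitrate = if (is.null(nitrate)) NULL else as.numeric(nitrate),
    sigma_theta = sw_sigma_theta(temperature, salinity),
    lon = lon, lat = lat, time = time), class = "ocean_profile")
}

#' @export
print.ocean_profile <- function(x, ...) {
  rng <- range(x$depth)
  cat(sprintf(
    "<ocean_profile> %d levels, %.1f-%.1f m, T %.2f-%.2f degC%s\n",
    length(x$depth), rng[1], rng[2], min(x$temperature), max(x$temperature),
    if (!is.null(x$nitrate)) ", with nitrate" else ""))
  invisible(x)
}

#' Mixed layer depth by density threshold
#'
#' Shallowest depth at which potential density exceeds its near-surface
#' value by `delta_sigma` (default 0.125 kg/m^3), linearly interpolated
#' between the bracketing samples. The "surface value" is the shallowest
#' valid sample, which must lie at or above `max_surface_depth` (ship CTDs
#' typically start at 3--5 m); otherwise the result is undefined.
#'
#' @param profile an [ocean_profile()]
#' @param delta_sigma density threshold, kg/m^3
#' @param max_surface_depth deepest admissible "surface" sample, m
#' @return list with `depth` (m or NA), `flag` (character: "ok",
#'   "no_crossing", "no_surface_sample", "surface_inversion")
#' @export
mixed_layer_depth <- function(profile, delta_sigma = 0.125,
                              max_surface_depth = 15) {
  z <- profile$depth
  s <- profile$sigma_theta
  ok <- is.finite(s)
  z <- z[ok]; s <- s[ok]
  if (length(z) < 2 || z[1] > max_surface_depth) {
    return(list(depth = NA_real_, flag = "no_surface_sample"))
  }
  flag <- "ok"
  if (any(s < s[1] - 1e-10)) flag <- "surface_inversion"
  target <- s[1] + delta_sigma
  above <- which(s >= target)
  if (length(above) == 0) return(list(depth = NA_real_, flag = "no_crossing"))
  i <- above[1]
  if (i == 1) return(list(depth = z[1], flag = flag))
  frac <- (target - s[i - 1]) / (s[i] - s[i - 1])
  list(depth = z[i - 1] + frac * (z[i] - z[i - 1]), flag = flag)
}

#' Isotherm depth
#'
#' Depth of the shallowest downward crossing of `t_iso` (default 20 degC,
#' the nitracline proxy) below the mixed layer, linearly interpolated
#' between the bracketing samples. Multiple crossings are resolved to the
#' shallowest and flagged, since the nitracline proxy is the upper boundary
#' of the cold, nitrate-rich water.
#'
#' @param profile an [ocean_profile()]
#' @param t_iso isotherm temperature, degC
#' @param below depth above which crossings are ignored (typically the mixed
#'   layer depth); default 0
#' @return list with `depth` (m or NA), `flag` ("ok", "no_crossing",
#'   "multiple_crossings")
#' @export
isotherm_depth <- function(profile, t_iso = 20, below = 0) {
  z <- profile$depth
  t <- profile$temperature
  ok <- is.finite(t)
  z <- z[ok]; t <- t[ok]
  if (length(z) < 2) return(list(depth = NA_real_, flag = "no_crossing"))
  # downward crossings: T above t_iso at the top of the interval, at or
  # below t_iso at the bottom
  cross <- which(t[-length(t)] > t_iso & t[-1] <= t_iso)
  cross <- cross[z[cross + 1] > below]
  if (length(cross) == 0) return(list(depth = NA_real_, flag = "no_crossing"))
  i <- cross[1]
  frac <- (t[i] - t_iso) / (t[i] - t[i + 1])
  list(depth = z[i] + frac * (z[i + 1] - z[i]),
       flag = if (length(cross) > 1) "multiple_crossings" else "ok")
}

#' Squared buoyancy frequency
#'
#' N^2 = g^2 rho (beta dS_A - alpha dT) / dP with the differences taken over
#' a centred running pressure window (default 10 dbar) and the expansion /
#' contraction coefficients evaluated locally from the package equation of
#' state. The result is returned on the input pressure grid; levels whose
#' window is incomplete are undefined.
#'
#' @param profile an [ocean_profile()]
#' @param window running-window width, dbar
#' @return numeric vector of N^2 (1/s^2) on the profile's grid
#' @export
buoyancy_frequency_squared <- function(profile, window = 10) {
  p <- profile$pressure
  t <- profile$temperature
  s <- profile$salinity
  g <- gravity(profile$lat)
  n <- length(p)
  half <- window / 2
  n2 <- rep(NA_real_, n)
  ok <- is.finite(t) & is.finite(s)
  for (i in seq_len(n)) {
    p_lo <- p[i] - half
    p_hi <- p[i] + half
    if (p_lo < p[1] - 1e-9 || p_hi > p[n] + 1e-9) next
    t_lo <- stats::approx(p[ok], t[ok], p_lo, ties = "ordered")$y
    t_hi <- stats::approx(p[ok], t[ok], p_hi, ties = "ordered")$y
    s_lo <- stats::approx(p[ok], s[ok], p_lo, ties = "ordered")$y
    s_hi <- stats::approx(p[ok], s[ok], p_hi, ties = "ordered")$y
    if (anyNA(c(t_lo, t_hi, s_lo, s_hi))) next
    rho <- sw_rho(t[i], s[i])
    alpha <- sw_alpha(t[i], s[i])
    beta <- sw_beta(t[i], s[i])
    dP_pa <- window * 1e4                 # dbar -> Pa
    n2[i] <- g^2 * rho * (beta * (s_hi - s_lo) - alpha * (t_hi - t_lo)) / dP_pa
  }
  n2
}

#' Regrid a profile onto a uniform pressure grid
#'
#' Linear interpolation of temperature, salinity and nitrate onto `grid`
#' (default 0:200 dbar at 1-dbar steps). No extrapolation: grid points
#' outside the observed pressure range are undefined. Optionally masks grid
#' points shallower than the profile's mixed layer depth.
#'
#' @param profile an [ocean_profile()]
#' @param grid target pressure grid, dbar
#' @param mask_mixed_layer set levels shallower than the detected mixed
#'   layer depth to NA
#' @return an `ocean_profile` on the new grid
#' @export
regrid_pressure <- function(profile, grid = 0:200, mask_mixed_layer = FALSE) {
  p <- profile$pressure
  li <- function(v) {
    if (is.null(v)) return(NULL)
    out <- stats::approx(p, v, grid, ties = "ordered", rule = 1)$y
    out
  }
  t_new <- li(profile$temperature)
  s_new <- li(profile$salinity)
  n_new <- li(profile$nitrate)
  if (mask_mixed_layer) {
    dml <- mixed_layer_depth(profile)$depth
    if (is.finite(dml)) {
      zgrid <- pressure_to_depth(grid, profile$lat)
      mask <- zgrid < dml
      t_new[mask] <- NA_real_
      s_new[mask] <- NA_real_
      if (!is.null(n_new)) n_new[mask] <- NA_real_
    }
  }
  out <- structure(list(
    depth = pressure_to_depth(grid, profile$lat), pressure = as.numeric(grid),
    temperature = t_new, salinity = s_new, nitrate = n_new,
    sigma_theta = sw_sigma_theta(t_new, s_new),
    lon = profile$lon, lat = profile$lat, time = profile$time),
    class = "ocean_profile")
  out
}

#' Default isopycnal grid
#'
#' 433 potential-density levels spanning 20.0--29.5 kg/m^3 with resolution
#' increasing towards higher densities: 0.025 kg/m^3 spacing up to
#' 28.0 kg/m^3 and ~0.0134 kg/m^3 beyond, where deep stratification is weak
#' and density changes slowly with depth.
#'
#' @return numeric vector of 433 sigma-theta levels
#' @export
isopycnal_grid_default <- function() {
  c(seq(20, 28, by = 0.025), seq(28, 29.5, length.out = 113)[-1])
}

#' Regrid a profile onto an isopycnal grid
#'
#' Temperature, salinity and pressure as functions of potential density on
#' `grid`, interpolated with the overshoot-suppressing modified-Akima scheme
#' ([interp_makima()]). Density inversions are removed beforehand by a
#' running maximum (interpolation needs a monotone abscissa); affected
#' levels are reported in `n_monotonized`. Grid levels outside the observed
#' density range are undefined.
#'
#' @param profile an [ocean_profile()]
#' @param grid sigma-theta levels, kg/m^3 (default [isopycnal_grid_default()])
#' @return list with `sigma_theta` (the grid), `temperature`, `salinity`,
#'   `pressure` on the grid, and `n_monotonized`
#' @export
regrid_isopycnal <- function(profile, grid = isopycnal_grid_default()) {
  sg <- profile$sigma_theta
  ok <- is.finite(sg)
  sg_ok <- sg[ok]
  mono <- cummax(sg_ok)
  n_fixed <- sum(mono > sg_ok + 1e-12)
  # collapse exact ties created by the running maximum (keep the first)
  keep <- c(TRUE, diff(mono) > 0)
  ab <- mono[keep]
  f <- function(v) interp_makima(ab, v[ok][keep], grid)
  list(sigma_theta = grid,
       temperature = f(profile$temperature),
       salinity = f(profile$salinity),
       pressure = f(profile$pressure),
       n_monotonized = n_fixed)
}
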