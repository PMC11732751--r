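# Shared fixtures and independent oracles, built in code.

# Profile with a prescribed potential-density profile: temperature held at
# the EOS reference (15 degC) and salinity inverted from the (linear-in-S)
# equation of state, so linear interpolation in sigma is exact.
profile_from_sigma <- function(depth, sigma) {
  rho0 <- 1026
  b0 <- 7.5e-4
  s <- 35 + ((sigma + 1000) / rho0 - 1) / b0
  ocean_profile(depth = depth, temperature = rep(15, length(depth)),
                salinity = s)
}

profile_from_t <- function(depth, temperature, salinity = 35) {
  ocean_profile(depth = depth, temperature = temperature,
                salinity = rep(salinity, length(depth)))
}

gauss_jet <- function(z, zc, w, U) U * exp(-((z - zc) / w)^2)

# signed circular day-of-year difference in (-182.5, 182.5]
circ_diff <- function(a, b) ((a - b + 182.5) %% 365) - 182.5

# annual-harmonic amplitude and phase (day of maximum) fitted to a
# seasonal climatology by ordinary least squares
harm_fit <- function(clim) {
  ok <- is.finite(clim$value)
  th <- 2 * pi * clim$phase[ok] / 365
  co <- qr.solve(cbind(1, cos(th), sin(th)), clim$value[ok])
  c(amp = sqrt(co[2]^2 + co[3]^2),
    phase = (atan2(co[3], co[2]) * 365 / (2 * pi)) %% 365,
    mean = co[1])
}

# attenuation of a 365-day harmonic by a uniform +/- half_window average
window_attenuation <- function(half_window, period = 365) {
  x <- 2 * pi * half_window / period
  sin(x) / x
}

# brute-force dense-grid argmax of an analytic jet
dense_argmax <- function(f, lower = 20, upper = 150, dz = 0.01) {
  z <- seq(lower, upper, by = dz)
  z[which.max(f(z))]
}
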