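#' Simplified seawater equation of state
#'
#' Compact equation of state for the tropical upper ocean (T 10--30 degC,
#' S_A 34--37 g/kg, upper few hundred dbar), quadratic in temperature and
#' linear in salinity:
#' \deqn{\rho(T, S_A) = \rho_0 [1 - \alpha_0 \Delta T - \tfrac{1}{2}\alpha_1
#'   \Delta T^2 + \beta_0 \Delta S]}
#' with \eqn{\Delta T = T - 15}, \eqn{\Delta S = S_A - 35},
#' \eqn{\rho_0 = 1026\,\mathrm{kg\,m^{-3}}},
#' \eqn{\alpha_0 = 2.1\times10^{-4}\,\mathrm{K^{-1}}},
#' \eqn{\alpha_1 = 9\times10^{-6}\,\mathrm{K^{-2}}},
#' \eqn{\beta_0 = 7.5\times10^{-4}\,\mathrm{(g/kg)^{-1}}}.
#' The thermal expansion coefficient \eqn{\alpha(T) = \alpha_0 + \alpha_1
#' \Delta T} then spans 1.7e-4 at 10 degC to 3.0e-4 at 25 degC, the observed
#' tropical range. Pressure dependence is neglected; all densities are
#' potential densities referenced to the surface.
#'
#' @param temperature conservative temperature, degC
#' @param salinity absolute salinity, g/kg
#' @return `sw_sigma_theta`: potential density anomaly, kg/m^3;
#'   `sw_rho`: in-situ (potential) density, kg/m^3; `sw_alpha`: thermal
#'   expansion coefficient, 1/K; `sw_beta`: haline contraction coefficient,
#'   kg/g.
#' @export
sw_sigma_theta <- function(temperature, salinity) {
  sw_rho(temperature, salinity) - 1000
}

#' @rdname sw_sigma_theta
#' @export
sw_rho <- function(temperature, salinity) {
  dT <- temperature - .eos$T0
  dS <- salinity - .eos$S0
  .eos$rho0 * (1 - .eos$a0 * dT - 0.5 * .eos$a1 * dT^2 + .eos$b0 * dS)
}

#' @rdname sw_sigma_theta
#' @export
sw_alpha <- function(temperature, salinity) {
  # alpha = -(1/rho) d rho/dT; the rho in the denominator varies by < 1 %
  # over the valid range, so the leading expression is alpha0 + alpha1*dT
  dT <- temperature - .eos$T0
  dS <- salinity - .eos$S0
  (.eos$a0 + .eos$a1 * dT) /
    (1 - .eos$a0 * dT - 0.5 * .eos$a1 * dT^2 + .eos$b0 * dS)
}

#' @rdname sw_sigma_theta
#' @export
sw_beta <- function(temperature, salinity) {
  dT <- temperature - .eos$T0
  dS <- salinity - .eos$S0
  .eos$b0 / (1 - .eos$a0 * dT - 0.5 * .eos$a1 * dT^2 + .eos$b0 * dS)
}

.eos <- list(rho0 = 1026, T0 = 15, S0 = 35,
             a0 = 2.1e-4, a1 = 9e-6, b0 = 7.5e-4)

#' Kinematic viscosity of seawater
#'
#' Exponential fit to seawater kinematic viscosity over 0--30 degC:
#' nu(T) = 1.79e-6 * exp(-0.0266 T) m^2/s, giving 1.05e-6 at 20 degC and
#' 9.2e-7 at 25 degC (within ~3 % of tabulated values at salinity 35).
#'
#' @param temperature in-situ temperature, degC
#' @return kinematic viscosity, m^2/s
#' @export
sw_viscosity <- function(temperature) {
  1.79e-6 * exp(-0.0266 * temperature)
}

#' Depth--pressure conversion
#'
#' Hydrostatic conversion with latitude-dependent gravity and a constant
#' reference density of 1025 kg/m^3, adequate to < 0.5 % over the upper
#' 500 m that this package addresses. Depth is positive downward in metres,
#' pressure in dbar.
#'
#' @param depth depth, m (positive down)
#' @param pressure pressure, dbar
#' @param latitude latitude, degrees (default 0, the equator)
#' @return converted axis
#' @export
depth_to_pressure <- function(depth, latitude = 0) {
  depth * 1025 * gravity(latitude) / 1e4
}

#' @rdname depth_to_pressure
#' @export
pressure_to_depth <- function(pressure, latitude = 0) {
  pressure * 1e4 / (1025 * gravity(latitude))
}

#' @rdname depth_to_pressure
#' @export
gravity <- function(latitude = 0) {
  s2 <- sin(latitude * pi / 180)^2
  9.780327 * (1 + 5.3024e-3 * s2 - 5.8e-6 * (2 * s2 - s2^2))
}
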