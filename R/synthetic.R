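#' Synthetic cruise-section scenario
#'
#' Parameters for an idealized trans-basin equatorial section: a Gaussian
#' eastward jet (the EUC) whose core depth and speed may vary with
#' longitude, a tanh thermocline carrying a monotone temperature--nitrate
#' relation, and a dissipation field with enhanced values in the sheared
#' layer above the jet core. All ground truths (core depth, 20 degC depth,
#' epsilon field) are recorded for recovery tests.
#'
#' Two presets bracket the observed seasonal extremes of the equatorial
#' Atlantic: [scenario_april()] (shallow, fast core at 53 m; nitracline well
#' below the core; moderate deep-cycle turbulence) and [scenario_september()]
#' (deep 91-m core, slower; nitracline in the shear zone above the core;
#' enhanced deep-cycle turbulence).
#'
#' @param n_stations number of stations
#' @param lon_range western/eastern limits, degrees
#' @param depth_grid CTD depth grid, m (default 0:200 at 1 m)
#' @param euc_core_depth core depth, m: a constant or a function of lon
#' @param euc_core_speed core speed, m/s: constant or function of lon
#' @param euc_width_z Gaussian e-folding half-width of the jet, m
#' @param thermocline_depth depth of the 20 degC isotherm, m: constant or
#'   function of lon
#' @param thermocline_width tanh width of the thermocline, m
#' @param t_surface,t_deep surface / deep temperature, degC (their midpoint
#'   sits at `thermocline_depth`; defaults 27 and 13 put 20 degC there)
#' @param ml_depth depth of the shallow halocline that bounds the surface
#'   mixed layer, m; realised as a salinity step so the 20 degC depth is
#'   untouched
#' @param ml_sal_step salinity increase across the halocline, g/kg (0.3
#'   gives a ~0.24 kg/m^3 density step, comfortably beyond the 0.125
#'   detection threshold)
#' @param ml_width tanh width of the halocline, m
#' @param sal_gradient background salinity increase with depth, g/kg per m;
#'   keeps the water column weakly stratified (N^2 ~ 2e-5 1/s^2) between
#'   halocline and thermocline, as observed, without moving the 20 degC
#'   isotherm
#' @param nitrate_relation monotone non-increasing map degC -> umol/kg;
#'   default piecewise-linear, zero above 20 degC and rising at
#'   2.5 umol/kg per degC of cooling below it
#' @param eps_deep_cycle peak dissipation enhancement in the deep cycle
#'   layer above the core, W/kg
#' @param eps_below_frac dissipation enhancement below the core, as a
#'   fraction of `eps_deep_cycle` (the jet's lower flank is also sheared;
#'   the quiet core in between acts as a mixing barrier)
#' @param eps_background background dissipation, W/kg
#' @param noise_sd named list of observation noise SDs: `t` (degC), `s`
#'   (g/kg), `no3` (umol/kg), `u` (m/s)
#' @param seed RNG seed
#' @return object of class `section_scenario`
#' @export
section_scenario <- function(n_stations = 12,
                             lon_range = c(-35, 2),
                             depth_grid = 0:200,
                             euc_core_depth = 53,
                             euc_core_speed = 1.0,
                             euc_width_z = 30,
                             thermocline_depth = 110,
                             thermocline_width = 15,
                             t_surface = 27, t_deep = 13,
                             ml_depth = 20, ml_sal_step = 0.3,
                             ml_width = 3, sal_gradient = 0.003,
                             nitrate_relation = NULL,
                             eps_deep_cycle = 5e-8,
                             eps_below_frac = 0.5,
                             eps_background = 1e-9,
                             noise_sd = list(t = 0.02, s = 0.005,
                                             no3 = 0.3, u = 0.02),
                             seed = 1) {
  if (is.null(nitrate_relation)) {
    nitrate_relation <- function(t) pmax(0, 2.5 * (20 - t))
  }
  as_fun <- function(x) if (is.function(x)) x else function(lon) rep(x, length(lon))
  scn <- list(n_stations = n_stations, lon_range = lon_range,
              depth_grid = depth_grid,
              euc_core_depth = as_fun(euc_core_depth),
              euc_core_speed = as_fun(euc_core_speed),
              euc_width_z = euc_width_z,
              thermocline_depth = as_fun(thermocline_depth),
              thermocline_width = thermocline_width,
              t_surface = t_surface, t_deep = t_deep,
              ml_depth = ml_depth, ml_sal_step = ml_sal_step,
              ml_width = ml_width, sal_gradient = sal_gradient,
              nitrate_relation = nitrate_relation,
              eps_deep_cycle = eps_deep_cycle,
              eps_below_frac = eps_below_frac,
              eps_background = eps_background,
              noise_sd = noise_sd, seed = seed)
  lons <- seq(lon_range[1], lon_range[2], length.out = n_stations)
  num <- c(scn$euc_core_depth(lons), scn$euc_core_speed(lons),
           euc_width_z, scn$thermocline_depth(lons), thermocline_width,
           t_surface, t_deep, ml_depth, ml_sal_step, ml_width, sal_gradient,
           eps_deep_cycle, eps_background, unlist(noise_sd))
  stopifnot_finite(scenario_parameters = num)
  if (is.unsorted(depth_grid, strictly = TRUE)) {
    stop("depth grid must be strictly increasing")
  }
  cd <- scn$euc_core_depth(lons)
  if (any(cd <= 20 | cd >= 150)) stop("euc core depth must lie in (20, 150) m")
  if (eps_deep_cycle <= 0 || eps_background <= 0 || eps_below_frac < 0) {
    stop("dissipation values must be positive")
  }
  tt <- seq(t_deep, t_surface, length.out = 50)
  if (any(diff(nitrate_relation(tt)) > 1e-9)) {
    stop("nitrate relation must be non-increasing in temperature")
  }
  class(scn) <- "section_scenario"
  scn
}

#' @rdname section_scenario
#' @export
scenario_april <- function(...) {
  section_scenario(euc_core_depth = 53, euc_core_speed = 1.0,
                   thermocline_depth = 110, eps_deep_cycle = 5e-8, ...)
}

#' @rdname section_scenario
#' @param ... overrides passed to [section_scenario()]
#' @export
scenario_september <- function(...) {
  section_scenario(euc_core_depth = 91, euc_core_speed = 0.8,
                   thermocline_depth = 60, eps_deep_cycle = 3e-7, ...)
}

#' Generate a synthetic cruise section
#'
#' Builds per-station temperature/salinity/nitrate profiles on the scenario
#' depth grid, a zonal velocity section on the native ADCP grid (8-m bins,
#' shallowest at 17 m) and the ground-truth record. Temperature follows a
#' tanh thermocline centred at the scenario's 20 degC depth; salinity rises
#' mildly across the thermocline (stably) and carries a sharper step at the
#' scenario's mixed-layer depth so the density-threshold detector has a
#' well-defined target; nitrate is the scenario relation
#' applied to the noise-free temperature; u is a Gaussian jet centred on the
#' core depth; v is zero. The truth dissipation field is the background
#' plus a Gaussian deep-cycle bump centred 20 m above the jet core (width
#' 12 m) and a weaker bump 20 m below it, emulating the observed mixing on
#' both jet flanks with a quiet core in between.
#'
#' @param scenario a [section_scenario()]
#' @return list with `profiles` (list of [ocean_profile()]), `velocity`
#'   (a [velocity_field()] on the 8-m ADCP grid), `truth` (list: `lon`,
#'   `core_depth`, `core_speed`, `d20`, `d_ml` (threshold depth of the
#'   noise-free density profile), `eps` function(depth, station),
#'   `eps_field` matrix on the CTD grid)
#' @export
make_section <- function(scenario) {
  stopifnot(inherits(scenario, "section_scenario"))
  with_seed(scenario$seed, {
    lons <- seq(scenario$lon_range[1], scenario$lon_range[2],
                length.out = scenario$n_stations)
    z <- scenario$depth_grid
    z_adcp <- seq(17, max(z), by = 8)
    cd <- scenario$euc_core_depth(lons)
    cs <- scenario$euc_core_speed(lons)
    ztc <- scenario$thermocline_depth(lons)
    tmid <- (scenario$t_surface + scenario$t_deep) / 2
    eps_fun <- function(depth, j) {
      scenario$eps_background + scenario$eps_deep_cycle *
        (exp(-((depth - (cd[j] - 20)) / 12)^2) +
           scenario$eps_below_frac * exp(-((depth - (cd[j] + 20)) / 12)^2))
    }
    profiles <- vector("list", scenario$n_stations)
    u <- matrix(NA_real_, length(z_adcp), scenario$n_stations)
    eps_field <- matrix(NA_real_, length(z), scenario$n_stations)
    d_ml_truth <- numeric(scenario$n_stations)
    t_of <- function(depth, j) {
      scenario$t_deep + (scenario$t_surface - scenario$t_deep) / 2 *
        (1 - tanh((depth - ztc[j]) / scenario$thermocline_width))
    }
    s_of <- function(depth, j) {
      35.2 + 0.5 * (scenario$t_surface - t_of(depth, j)) /
        (scenario$t_surface - scenario$t_deep) +
        scenario$ml_sal_step *
        (1 + tanh((depth - scenario$ml_depth) / scenario$ml_width)) / 2 +
        scenario$sal_gradient * depth
    }
    for (j in seq_len(scenario$n_stations)) {
      t_clean <- t_of(z, j)
      s_clean <- s_of(z, j)
      no3_clean <- scenario$nitrate_relation(t_clean)
      # construction truth for the mixed layer: threshold crossing of the
      # noise-free density profile
      sig0 <- sw_sigma_theta(t_of(0, j), s_of(0, j))
      d_ml_truth[j] <- stats::uniroot(function(zz) {
        sw_sigma_theta(t_of(zz, j), s_of(zz, j)) - sig0 - 0.125
      }, c(0, max(z)))$root
      profiles[[j]] <- ocean_profile(
        depth = z,
        temperature = t_clean + stats::rnorm(length(z), 0, scenario$noise_sd$t),
        salinity = s_clean + stats::rnorm(length(z), 0, scenario$noise_sd$s),
        nitrate = pmax(0, no3_clean +
                         stats::rnorm(length(z), 0, scenario$noise_sd$no3)),
        lon = lons[j], lat = 0, time = j)
      u[, j] <- cs[j] * exp(-((z_adcp - cd[j]) / scenario$euc_width_z)^2) +
        stats::rnorm(length(z_adcp), 0, scenario$noise_sd$u)
      eps_field[, j] <- eps_fun(z, j)
    }
    list(profiles = profiles,
         velocity = velocity_field(z_adcp, lons, u,
                                   provenance = "shipboard"),
         truth = list(lon = lons, core_depth = cd, core_speed = cs,
                      d20 = ztc, d_ml = d_ml_truth, eps = eps_fun,
                      eps_field = eps_field))
  })
}

#' Synthesize a microstructure shear record with a Nasmyth spectrum
#'
#' Random-phase Fourier synthesis of a shear time series whose one-sided
#' wavenumber spectrum equals the Nasmyth form at `eps_true`: spectral
#' amplitudes are Rayleigh-distributed around the target density (a Gaussian
#' process), phases uniform, and the frequency axis maps to wavenumber by
#' the fall speed under Taylor's frozen-turbulence hypothesis.
#'
#' @param eps_true target dissipation rate, W/kg; must lie in the oceanic
#'   range 1e-11 to 1e-4
#' @param nu kinematic viscosity, m^2/s
#' @param fall_speed profiler fall speed, m/s
#' @param duration record length, s
#' @param sample_rate sampling rate, Hz; the resolved wavenumber band
#'   (Nyquist frequency / fall speed) must reach at least 30 cpm so the
#'   default integration band of the estimator is covered
#' @param seed RNG seed
#' @param temperature in-situ temperature stored on the record, degC
#' @param depth nominal segment depth stored on the record, m
#' @return a [shear_record()]
#' @export
make_shear_record <- function(eps_true, nu = 1.05e-6, fall_speed = 0.55,
                              duration = 120, sample_rate = 128, seed = NULL,
                              temperature = 20, depth = NA_real_) {
  if (!is.finite(eps_true) || eps_true < 1e-11 || eps_true > 1e-4) {
    stop("eps_true outside the oceanic range [1e-11, 1e-4] W/kg")
  }
  stopifnot(nu > 0, fall_speed > 0.1, duration > 0, sample_rate > 0)
  if (sample_rate / (2 * fall_speed) < 30) {
    stop("sample_rate too low: resolved band must reach 30 cpm")
  }
  n <- round(duration * sample_rate)
  df <- sample_rate / n
  shear <- with_seed(seed, {
    nf <- floor((n - 1) / 2)             # positive frequencies below Nyquist
    f <- (1:nf) * df
    k <- f / fall_speed
    phi_f <- nasmyth_spectrum(eps_true, nu, k) / fall_speed  # per cpm -> per Hz
    # E|A|^2 = phi_f * df / 2 per one-sided pair; Rayleigh amplitudes
    a <- sqrt(phi_f * df / 4) *
      complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf))
    spec <- complex(real = numeric(n))
    spec[2:(nf + 1)] <- a
    spec[n:(n - nf + 1)] <- Conj(a)
    Re(stats::fft(spec, inverse = TRUE))
  })
  shear_record(shear, sample_rate = sample_rate, fall_speed = fall_speed,
               temperature = temperature, depth = depth)
}

#' Synthetic mooring scenario and generator
#'
#' Daily time series of EUC core depth and 20 degC isotherm depth built as
#' mean + annual + semiannual harmonics + AR(1) red noise with a prescribed
#' e-folding decorrelation timescale. Harmonic phases are the day-of-year of
#' the maximum (deepest excursion). Defaults emulate the eastern-basin
#' phasing: the core is deepest in late September and shallowest in boreal
#' spring, while the isotherm (nitracline proxy) is shallowest in July, so
#' their difference peaks in June--August.
#'
#' @param duration_days record length, days (default 6 years)
#' @param cadence sample spacing, days
#' @param d_euc,d_20 lists with `mean` (m), `annual_amp` (m),
#'   `annual_phase` (day of maximum), `semiannual_amp` (m),
#'   `semiannual_phase` (day of maximum)
#' @param noise_sd red-noise standard deviation, m
#' @param timescale AR(1) e-folding decorrelation timescale, days; must be
#'   at least the cadence
#' @param seed RNG seed
#' @return `mooring_scenario`: object of class `mooring_scenario`.
#'   `make_mooring`: list with `time` (days), `doy`, `d_euc`, `d_20`
#'   (numeric series) and `truth` (the scenario harmonics).
#' @export
mooring_scenario <- function(duration_days = 6 * 365, cadence = 1,
                             d_euc = list(mean = 70, annual_amp = 20,
                                          annual_phase = 270,
                                          semiannual_amp = 4,
                                          semiannual_phase = 30),
                             d_20 = list(mean = 65, annual_amp = 15,
                                         annual_phase = 15,
                                         semiannual_amp = 3,
                                         semiannual_phase = 60),
                             noise_sd = 6, timescale = 10, seed = 1) {
  for (h in list(d_euc, d_20)) {
    if (h$annual_amp + h$semiannual_amp >= h$mean) {
      stop("harmonic amplitudes must stay below the mean depth")
    }
  }
  if (timescale < cadence) stop("decorrelation timescale must be >= cadence")
  structure(list(duration_days = duration_days, cadence = cadence,
                 d_euc = d_euc, d_20 = d_20, noise_sd = noise_sd,
                 timescale = timescale, seed = seed),
            class = "mooring_scenario")
}

harmonic_series <- function(doy, h) {
  h$mean + h$annual_amp * cos(2 * pi * (doy - h$annual_phase) / 365) +
    h$semiannual_amp * cos(4 * pi * (doy - h$semiannual_phase) / 365)
}

ar1_series <- function(n, sd, timescale, cadence = 1) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-cadence / timescale)
  as.numeric(stats::arima.sim(list(ar = phi), n = n,
                              sd = sd * sqrt(1 - phi^2)))
}

#' @rdname mooring_scenario
#' @param scenario a `mooring_scenario`
#' @export
make_mooring <- function(scenario) {
  stopifnot(inherits(scenario, "mooring_scenario"))
  with_seed(scenario$seed, {
    time <- seq(0, scenario$duration_days - 1, by = scenario$cadence)
    doy <- fold_doy(time + 1)
    n <- length(time)
    d_euc <- harmonic_series(doy, scenario$d_euc) +
      ar1_series(n, scenario$noise_sd, scenario$timescale, scenario$cadence)
    d_20 <- harmonic_series(doy, scenario$d_20) +
      ar1_series(n, scenario$noise_sd, scenario$timescale, scenario$cadence)
    list(time = time, doy = doy, d_euc = d_euc, d_20 = d_20,
         truth = list(d_euc = scenario$d_euc, d_20 = scenario$d_20,
                      timescale = scenario$timescale,
                      noise_sd = scenario$noise_sd))
  })
}

#' Synthetic Argo-like profile cloud
#'
#' Scattered (lon, lat, time, value) observations around a site: a planted
#' seasonal harmonic plus linear longitude, linear + quadratic latitude
#' gradients and iid Gaussian noise, with positions uniform in the sampling
#' ellipse used by the climatology (8 degrees in longitude, 3 in latitude).
#'
#' @param site c(lon, lat) of the nominal site, degrees
#' @param n_profiles number of profiles (>= 50)
#' @param lon_slope value change per degree longitude east of the site
#' @param lat_slope,lat_quad linear and quadratic latitude terms (per degree
#'   and per degree^2)
#' @param harmonic list(mean, amp, phase): planted seasonal cycle, `phase`
#'   the day-of-year of the maximum
#' @param noise_sd iid observation noise SD
#' @param ellipse c(lon_radius, lat_radius), degrees
#' @param span_years sampling period, years
#' @param seed RNG seed
#' @return list with `data` (data.frame: lon, lat, time, doy, value) and
#'   `truth`
#' @export
make_argo_cloud <- function(site = c(-10, 0), n_profiles = 400,
                            lon_slope = 0, lat_slope = 0, lat_quad = 0,
                            harmonic = list(mean = 50, amp = 10, phase = 195),
                            noise_sd = 3, ellipse = c(8, 3),
                            span_years = 10, seed = 1) {
  if (n_profiles < 50) stop("need at least 50 profiles")
  with_seed(seed, {
    dlon <- dlat <- numeric(0)
    while (length(dlon) < n_profiles) {
      m <- 2 * (n_profiles - length(dlon)) + 10
      a <- stats::runif(m, -ellipse[1], ellipse[1])
      b <- stats::runif(m, -ellipse[2], ellipse[2])
      keep <- (a / ellipse[1])^2 + (b / ellipse[2])^2 <= 1
      dlon <- c(dlon, a[keep]); dlat <- c(dlat, b[keep])
    }
    dlon <- dlon[seq_len(n_profiles)]; dlat <- dlat[seq_len(n_profiles)]
    time <- stats::runif(n_profiles, 0, span_years * 365)
    doy <- fold_doy(floor(time) + 1)
    value <- harmonic$mean +
      harmonic$amp * cos(2 * pi * (doy - harmonic$phase) / 365) +
      lon_slope * dlon + lat_slope * dlat + lat_quad * dlat^2 +
      stats::rnorm(n_profiles, 0, noise_sd)
    list(data = data.frame(lon = site[1] + dlon, lat = site[2] + dlat,
                           time = time, doy = doy, value = value),
         truth = list(site = site, lon_slope = lon_slope,
                      lat_slope = lat_slope, lat_quad = lat_quad,
                      harmonic = harmonic, noise_sd = noise_sd))
  })
}
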