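test_that("mixed layer depth matches analytic constructions", {
  # sharp two-layer step at 40 m
  z <- c(seq(0, 39.9, by = 2), 39.999, 40.001, seq(42, 100, by = 2))
  sigma <- ifelse(z <= 40, 23.0, 23.5)
  p <- profile_from_sigma(z, sigma)
  expect_equal(mixed_layer_depth(p)$depth, 40, tolerance = 1e-3)

  # linear gradient: 0.125 / (1.0 per 100 m) = 12.5 m
  z <- 0:100
  p <- profile_from_sigma(z, 23 + z / 100)
  res <- mixed_layer_depth(p)
  expect_equal(res$depth, 12.5, tolerance = 1e-9)
  expect_identical(res$flag, "ok")

  # uniform density never crosses the threshold
  p <- profile_from_sigma(0:100, rep(23, 101))
  res <- mixed_layer_depth(p)
  expect_true(is.na(res$depth))
  expect_identical(res$flag, "no_crossing")

  # no valid sample shallower than 15 m
  p <- profile_from_sigma(seq(20, 100, 5), seq(23, 24, length.out = 17))
  expect_identical(mixed_layer_depth(p)$flag, "no_surface_sample")

  # surface inversion is flagged but still yields a depth
  sig <- c(23.1, 23.05, 23.0, seq(23.0, 24, length.out = 18))
  p <- profile_from_sigma(seq(0, 100, 5), sig)
  expect_identical(mixed_layer_depth(p)$flag, "surface_inversion")
})

test_that("layer detectors are exact on random piecewise-linear profiles", {
  set.seed(31)
  for (i in 1:25) {
    z_break <- runif(1, 20, 60)
    slope1 <- runif(1, 0, 0.002)      # weak upper gradient
    slope2 <- runif(1, 0.02, 0.08)    # pycnocline gradient
    z <- sort(c(0, z_break, runif(30, 0, 150), 150))
    sigma <- 23 + ifelse(z <= z_break, slope1 * z,
                         slope1 * z_break + slope2 * (z - z_break))
    p <- profile_from_sigma(z, sigma)
    # analytic 0.125 crossing
    d_ml_true <- if (slope1 * z_break >= 0.125) 0.125 / slope1 else {
      z_break + (0.125 - slope1 * z_break) / slope2
    }
    expect_lt(abs(mixed_layer_depth(p)$depth - d_ml_true), 0.01)

    # piecewise-linear temperature crossing 20 degC
    t_break <- runif(1, 60, 120)
    tslope <- runif(1, 0.1, 0.5)
    # the kink must be a sample for the piecewise line to be exact under
    # linear interpolation
    tz <- sort(c(0, t_break, runif(40, 0, 200), 200))
    temp <- ifelse(tz <= t_break, 24, 24 - tslope * (tz - t_break))
    d20_true <- t_break + 4 / tslope
    if (d20_true < 200) {
      pt <- profile_from_t(tz, temp)
      expect_lt(abs(isotherm_depth(pt)$depth - d20_true), 0.01)
    }
  }
})

test_that("isotherm depth handles the stated examples and flags", {
  p <- profile_from_t(c(0, 50, 70, 100), c(26, 22, 18, 15))
  expect_equal(isotherm_depth(p)$depth, 60, tolerance = 1e-9)

  p_warm <- profile_from_t(c(0, 50, 100), c(28, 26, 24))
  expect_true(is.na(isotherm_depth(p_warm)$depth))
  expect_identical(isotherm_depth(p_warm)$flag, "no_crossing")

  # non-monotone profile: shallowest crossing wins, flagged
  p_multi <- profile_from_t(c(0, 40, 60, 80, 100, 150),
                            c(25, 19, 21, 19, 15, 12))
  res <- isotherm_depth(p_multi)
  expect_identical(res$flag, "multiple_crossings")
  expect_lt(res$depth, 45)
})

test_that("20 degC depth is recovered from a planted synthetic thermocline", {
  scn <- section_scenario(n_stations = 5, thermocline_depth = 91, seed = 4)
  sec <- make_section(scn)
  for (p in sec$profiles) {
    expect_lt(abs(isotherm_depth(p)$depth - 91), 0.5)
  }
})

test_that("N^2 is zero for homogeneous water and matches the density-gradient oracle", {
  z <- 0:120
  p <- profile_from_t(z, rep(18, length(z)))
  n2 <- buoyancy_frequency_squared(p)
  expect_true(all(abs(n2[is.finite(n2)]) < 1e-12))

  # linear temperature decrease, constant salinity
  p <- profile_from_t(z, 28 - 0.1 * z)
  n2 <- buoyancy_frequency_squared(p)
  # magnitude around g * alpha * 0.1 ~ 3e-4 1/s^2
  mid <- 40:80
  expect_true(all(n2[mid] > 1e-4 & n2[mid] < 6e-4))
  # independent oracle: N^2 = (g/rho) dsigma/dz, centred differences
  g <- equaflux::gravity(0)
  sig <- p$sigma_theta
  for (i in seq(30, 90, by = 10)) {
    oracle <- g / (1000 + sig[i]) * (sig[i + 5] - sig[i - 5]) /
      (p$depth[i + 5] - p$depth[i - 5])
    expect_equal(n2[i], oracle, tolerance = 0.05)
  }

  # inversion layer gives negative N^2
  tt <- 28 - 0.1 * z
  tt[50:60] <- tt[50:60] + 1.5    # warm (light) anomaly at depth -> unstable top edge
  p_inv <- profile_from_t(z, tt)
  n2_inv <- buoyancy_frequency_squared(p_inv)
  expect_true(any(n2_inv < 0, na.rm = TRUE))
})

test_that("pressure regridding interpolates linearly without extrapolation", {
  p <- ocean_profile(pressure = c(0, 10, 20, 40), temperature = c(28, 26, 22, 18),
                     salinity = c(35, 35.1, 35.3, 35.6))
  g <- regrid_pressure(p, grid = c(0, 5, 10, 30, 40, 50))
  expect_equal(g$temperature[1], 28)                 # endpoint identity
  expect_equal(g$temperature[2], 27)                 # midpoint of linear segment
  expect_equal(g$temperature[4], 20)                 # midpoint 20-40
  expect_true(is.na(g$temperature[6]))               # no extrapolation

  # idempotence on data already on the target grid
  g2 <- regrid_pressure(g, grid = c(0, 5, 10, 30, 40, 50))
  expect_equal(g2$temperature, g$temperature)

  # mixed-layer masking
  z <- 0:100
  pm <- profile_from_sigma(z, 23 + z / 100)          # D_ML = 12.5 m
  gm <- regrid_pressure(pm, grid = 0:50, mask_mixed_layer = TRUE)
  shallow <- gm$depth < 12.4
  expect_true(all(is.na(gm$temperature[shallow])))
})

test_that("modified-Akima interpolation is linear-exact, node-exact and overshoot-free", {
  x <- c(0, 1, 2.5, 4, 7, 10)
  y <- 2 + 3 * x
  xo <- seq(0, 10, by = 0.1)
  expect_equal(interp_makima(x, y, xo), 2 + 3 * xo, tolerance = 1e-12)

  set.seed(5)
  y2 <- cumsum(abs(rnorm(6)))
  expect_equal(interp_makima(x, y2, x), y2, tolerance = 1e-12)

  # step-like data: no overshoot beyond the data range
  ys <- c(0, 0, 0, 1, 1, 1)
  dense <- interp_makima(x, ys, seq(0, 10, by = 0.001))
  expect_lte(max(dense), max(ys) + 1e-9)
  expect_gte(min(dense), min(ys) - 1e-9)

  # outside the abscissa -> NA
  expect_true(all(is.na(interp_makima(x, y, c(-1, 11)))))
})

test_that("isopycnal regridding reproduces node values and monotonizes inversions", {
  z <- seq(0, 200, by = 2)
  p <- profile_from_t(z, 28 - 0.07 * z)
  out <- regrid_isopycnal(p)
  expect_identical(out$n_monotonized, 0L)
  ok <- is.finite(out$temperature)
  expect_gt(sum(ok), 50)
  # inverse consistency: interpolated T at the profile's own densities
  idx <- which(ok)
  back <- approx(p$sigma_theta, p$temperature, out$sigma_theta[idx],
                 ties = "ordered")$y
  expect_equal(out$temperature[idx], back, tolerance = 1e-3)

  # density inversion is repaired and counted
  tt <- 28 - 0.07 * z
  tt[30:35] <- tt[30:35] - 1      # dense water above lighter -> inversion below
  p_inv <- profile_from_t(z, tt)
  out_inv <- regrid_isopycnal(p_inv)
  expect_gt(out_inv$n_monotonized, 0)
})

test_that("equation-of-state coefficients are mutually consistent", {
  # alpha and beta are the log-derivatives of the density polynomial
  for (tt in c(12, 18, 24, 28)) {
    for (ss in c(34.5, 35.5, 36.5)) {
      dT <- 1e-4
      a_num <- -(sw_rho(tt + dT, ss) - sw_rho(tt - dT, ss)) /
        (2 * dT * sw_rho(tt, ss))
      expect_equal(sw_alpha(tt, ss), a_num, tolerance = 1e-6)
      dS <- 1e-4
      b_num <- (sw_rho(tt, ss + dS) - sw_rho(tt, ss - dS)) /
        (2 * dS * sw_rho(tt, ss))
      expect_equal(sw_beta(tt, ss), b_num, tolerance = 1e-6)
    }
  }
  # viscosity decreases with temperature, right magnitude
  expect_equal(sw_viscosity(20), 1.05e-6, tolerance = 0.02)
  expect_gt(sw_viscosity(5), sw_viscosity(25))
})
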