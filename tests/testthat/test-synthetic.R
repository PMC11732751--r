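test_that("generators are deterministic under a fixed seed", {
  a <- make_section(section_scenario(n_stations = 3, seed = 5))
  b <- make_section(section_scenario(n_stations = 3, seed = 5))
  expect_identical(a$velocity$u, b$velocity$u)
  expect_identical(a$profiles[[2]]$temperature, b$profiles[[2]]$temperature)

  r1 <- make_shear_record(1e-9, duration = 10, seed = 3)
  r2 <- make_shear_record(1e-9, duration = 10, seed = 3)
  expect_identical(r1$shear, r2$shear)

  m1 <- make_mooring(mooring_scenario(seed = 4))
  m2 <- make_mooring(mooring_scenario(seed = 4))
  expect_identical(m1$d_euc, m2$d_euc)

  c1 <- make_argo_cloud(seed = 6)
  c2 <- make_argo_cloud(seed = 6)
  expect_identical(c1$data, c2$data)

  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_shear_record(1e-9, duration = 5, seed = 2))
  expect_identical(runif(1), before)
})

test_that("section construction truths are recoverable", {
  # constant core depth plants the truth at every station
  sec <- make_section(section_scenario(n_stations = 4, euc_core_depth = 53,
                                       seed = 2))
  expect_equal(sec$truth$core_depth, rep(53, 4))

  # core and thermocline at 91 m: detected depth difference is zero
  scn <- section_scenario(n_stations = 4, euc_core_depth = 91,
                          euc_core_speed = 0.8, thermocline_depth = 91,
                          seed = 3)
  sec <- make_section(scn)
  for (j in 1:4) {
    d20 <- isotherm_depth(sec$profiles[[j]])$depth
    core <- euc_core(sec$velocity$depth, sec$velocity$u[, j])$depth
    expect_lt(abs(core - d20), 1.5)
  }

  # the mixed-layer truth matches the detector on noise-free profiles
  scn0 <- section_scenario(n_stations = 2, noise_sd = list(t = 0, s = 0,
                                                           no3 = 0, u = 0),
                           seed = 1)
  sec0 <- make_section(scn0)
  dml <- mixed_layer_depth(sec0$profiles[[1]])$depth
  expect_lt(abs(dml - sec0$truth$d_ml[1]), 0.2)

  # invalid scenarios are rejected
  expect_error(section_scenario(euc_core_depth = 10), "20")
  expect_error(section_scenario(eps_background = -1), "positive")
  expect_error(section_scenario(nitrate_relation = function(t) t),
               "non-increasing")
})

test_that("synthesized shear spectra match the Nasmyth target in the band", {
  # ensemble-average periodogram over 50 records vs the target curve,
  # compared in four sub-bands of the integration band
  eps <- 1e-9
  nu <- sw_viscosity(20)
  n_rec <- 50
  acc <- NULL
  for (s in 1:n_rec) {
    rec <- make_shear_record(eps, nu = nu, duration = 10, seed = 400 + s)
    n <- length(rec$shear)
    xf <- fft(rec$shear) / n
    df <- rec$sample_rate / n
    psd <- 2 * Mod(xf[2:floor(n / 2)])^2 / df
    if (is.null(acc)) acc <- psd else acc <- acc + psd
  }
  psd_mean <- acc / n_rec
  n <- round(10 * 128)
  df <- 128 / n
  f <- (1:(floor(n / 2) - 1)) * df
  k <- f / 0.55
  target <- nasmyth_spectrum(eps, nu, k) / 0.55
  edges <- c(2, 5, 10, 18, 30)
  for (i in 1:4) {
    sel <- k >= edges[i] & k < edges[i + 1]
    ratio <- mean(psd_mean[sel]) / mean(target[sel])
    expect_lt(abs(ratio - 1), 0.1)
  }
})

test_that("shear synthesis validates its inputs", {
  expect_error(make_shear_record(1e-12), "oceanic range")
  expect_error(make_shear_record(1e-3), "oceanic range")
  expect_error(make_shear_record(1e-9, sample_rate = 16), "30 cpm")
})

test_that("mooring harmonics are recovered in the noiseless limit", {
  scn <- mooring_scenario(noise_sd = 0, seed = 1)
  m <- make_mooring(scn)
  clim <- mooring_seasonal_cycle(m$time, m$d_euc)
  hf <- harm_fit(clim)
  expect_equal(unname(hf["amp"]), scn$d_euc$annual_amp, tolerance = 0.02)
  expect_lt(abs(circ_diff(hf["phase"], scn$d_euc$annual_phase)), 2)
  expect_equal(unname(hf["mean"]), scn$d_euc$mean, tolerance = 0.01)

  # zero amplitude: climatology flat within noise-consistent errors
  scn0 <- mooring_scenario(d_euc = list(mean = 70, annual_amp = 0,
                                        annual_phase = 1,
                                        semiannual_amp = 0,
                                        semiannual_phase = 1),
                           noise_sd = 5, timescale = 10, seed = 8)
  m0 <- make_mooring(scn0)
  clim0 <- mooring_seasonal_cycle(m0$time, m0$d_euc)
  frac_ok <- mean(abs(clim0$value - mean(clim0$value)) <= 2.5 * clim0$se)
  expect_gt(frac_ok, 0.85)
})

test_that("AR(1) decorrelation timescale of mooring noise is recovered", {
  scales <- vapply(1:30, function(s) {
    scn <- mooring_scenario(d_euc = list(mean = 70, annual_amp = 0,
                                         annual_phase = 1,
                                         semiannual_amp = 0,
                                         semiannual_phase = 1),
                            noise_sd = 5, timescale = 10, seed = 100 + s)
    m <- make_mooring(scn)
    efold_decorrelation(m$d_euc - mean(m$d_euc))$scale
  }, numeric(1))
  expect_lt(abs(mean(scales) - 10), 3)
})

test_that("argo cloud climatology recovers planted structure", {
  # no gradients, no noise: entries equal the window-attenuated harmonic
  cl <- make_argo_cloud(n_profiles = 2000, noise_sd = 0,
                        harmonic = list(mean = 50, amp = 10, phase = 195),
                        seed = 3)
  clim <- argo_climatology(cl$data, site = c(-10, 0))
  att <- window_attenuation(45)
  expected <- 50 + att * 10 * cos(2 * pi * (clim$phase - 195) / 365)
  expect_lt(max(abs(clim$value - expected)), 1)

  # planted longitude slope recovered within 3 SE by the weighted fit
  cl2 <- make_argo_cloud(n_profiles = 400, lon_slope = 2, noise_sd = 3,
                         seed = 9)
  d <- cl2$data
  dk <- geosphere::distHaversine(cbind(d$lon, d$lat), c(-10, 0)) / 1000
  fit <- lm(value ~ I(lon + 10) + lat + I(lat^2), data = d,
            weights = exp(-dk^2 / (2 * 200^2)))
  est <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - 2), 3 * se)

  # outliers at 10 sigma are removed by the IQR filter
  set.seed(4)
  v <- rnorm(500, 50, 3)
  out_idx <- sample(500, 50)
  v[out_idx] <- v[out_idx] + sample(c(-1, 1), 50, TRUE) * 30
  keep <- equaflux:::iqr_keep(v)
  expect_gte(sum(!keep[out_idx]), 45)

  expect_error(make_argo_cloud(n_profiles = 10), "50")
})
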