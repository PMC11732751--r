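test_that("Nasmyth spectrum satisfies the isotropy identity and Kolmogorov scaling", {
  nu <- 1.05e-6
  for (eps in c(1e-10, 1e-9, 1e-7)) {
    total <- integrate(function(k) nasmyth_spectrum(eps, nu, k), 0, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(7.5 * nu * total, eps, tolerance = 0.01)
  }

  # non-dimensional collapse: Phi / (eps^{3/4} nu^{-1/4}) vs k/k_s is
  # independent of eps
  x <- 10^seq(-3, 0, length.out = 40)
  nd <- function(eps) {
    ks <- (eps / nu^3)^0.25
    nasmyth_spectrum(eps, nu, x * ks) / (eps^0.75 * nu^-0.25)
  }
  expect_equal(nd(1e-9), nd(4e-9), tolerance = 1e-12)
  expect_equal(nd(1e-9), nd(1e-7), tolerance = 1e-12)

  # finite and small at k = 0
  expect_identical(nasmyth_spectrum(1e-9, nu, 0), 0)
  expect_lt(nasmyth_spectrum(1e-9, nu, 1e-4),
            max(nasmyth_spectrum(1e-9, nu, c(1, 10, 50))))
})

test_that("band fraction integrates the Nasmyth form correctly", {
  nu <- 1.05e-6
  eps <- 1e-9
  # wide band resolves almost everything
  expect_gt(nasmyth_fraction(c(0.01, 1e4), eps, nu), 0.999)
  # fractions add up across adjacent bands
  f1 <- nasmyth_fraction(c(2, 30), eps, nu)
  f2 <- nasmyth_fraction(c(30, 100), eps, nu)
  f3 <- nasmyth_fraction(c(2, 100), eps, nu)
  expect_equal(f1 + f2, f3, tolerance = 1e-8)
})

test_that("dissipation estimates close the loop on synthesized records", {
  est <- vapply(1:12, function(s) {
    rec <- make_shear_record(1e-9, duration = 30, seed = s)
    epsilon_from_record(rec)$epsilon
  }, numeric(1))
  expect_lt(abs(mean(est) / 1e-9 - 1), 0.3)
  expect_true(all(est > 1e-9 / 5 & est < 1e-9 * 5))
})

test_that("full-band estimation reduces to the isotropy identity", {
  # independent oracle: plain rectangular-window periodogram of the raw
  # series, integrated over all resolved wavenumbers
  rec <- make_shear_record(1e-10, duration = 60, sample_rate = 256, seed = 3)
  n <- length(rec$shear)
  xf <- fft(rec$shear) / n
  df <- rec$sample_rate / n
  psd <- 2 * Mod(xf[2:floor(n / 2)])^2 / df
  k <- (1:(floor(n / 2) - 1)) * df / rec$fall_speed
  total_var <- sum(psd) * df
  frac <- nasmyth_fraction(range(k), 1e-10, sw_viscosity(20))
  eps_oracle <- 7.5 * sw_viscosity(20) * total_var / frac
  expect_equal(eps_oracle, 1e-10, tolerance = 0.25)

  # package estimator over a wide band agrees with the oracle route
  est <- epsilon_from_record(rec, band = c(1, 100))$epsilon
  expect_equal(est, 1e-10, tolerance = 0.3)
})

test_that("noise-floor and white-noise records are flagged, not mis-estimated", {
  # record at the lower oceanic bound: estimate stays near the floor
  rec <- make_shear_record(1e-11, duration = 30, sample_rate = 256, seed = 2)
  est <- epsilon_from_record(rec)$epsilon
  expect_lt(est, 3e-11)

  # white noise only: flagged as noise or saturated, never "ok"
  set.seed(6)
  flags <- vapply(1:5, function(i) {
    wn <- shear_record(rnorm(256, sd = 2e-3), 128, 0.55)
    epsilon_from_segment(wn)$flag
  }, character(1))
  expect_false(any(flags == "ok"))
})

test_that("depth-binned dissipation profiles average and bootstrap correctly", {
  # single segment and equal segments are identities
  pr <- profile_epsilon(c(1e-9, 1e-9), c(55, 55), breaks = c(50, 60))
  expect_equal(pr$epsilon, 1e-9)
  expect_equal(pr$n, 2L)

  set.seed(21)
  eps <- rlnorm(200, log(1e-9), 1)
  pr <- profile_epsilon(eps, rep(105, 200), breaks = c(100, 110), seed = 9)
  expect_equal(pr$epsilon, mean(eps))
  expect_true(pr$lower < mean(eps) && mean(eps) < pr$upper)

  # bootstrap CI covers the true mean of a lognormal population ~95 %
  cover <- 0
  mu_true <- exp(log(1e-9) + 0.5)
  set.seed(77)
  for (r in 1:150) {
    x <- rlnorm(150, log(1e-9), 1)
    ci <- bootstrap_mean_ci(x, reps = 600)
    cover <- cover + (ci[1] <= mu_true && mu_true <= ci[2])
  }
  expect_gt(cover / 150, 0.88)
  expect_lt(cover / 150, 0.99)
})

test_that("diffusivity and nitrate flux follow the Osborn and gradient relations", {
  expect_equal(diffusivity(1e-9, 1e-4), 2e-6)
  expect_equal(diffusivity(1e-8, 2e-5), 1e-4)
  expect_true(is.na(diffusivity(1e-9, 0)))
  expect_true(is.na(diffusivity(1e-9, -1e-5)))

  # symbolic-evaluation property on random positive inputs
  set.seed(14)
  for (i in 1:50) {
    eps <- 10^runif(1, -10, -7)
    n2 <- 10^runif(1, -6, -3)
    gam <- runif(1, 0.1, 0.3)
    expect_equal(diffusivity(eps, n2, gam), gam * eps / n2,
                 tolerance = 1e-14)
  }

  # exact linear nitrate profile: slope recovered exactly, flux = K * slope
  z <- seq(60, 74, by = 2)
  no3 <- 3 + 0.1 * z
  fl <- nitrate_flux(1e-4, no3, z, rep(1, length(z)), rho = 1025)
  expect_equal(fl$gradient, 0.1, tolerance = 1e-12)
  expect_equal(fl$flux, 1e-5, tolerance = 1e-12)
  expect_equal(fl$flux_mmol_m2_s, 1e-5 * 1025 / 1000, tolerance = 1e-12)

  # zero gradient -> zero flux; too few samples -> undefined
  fl0 <- nitrate_flux(1e-4, rep(5, 8), z, rep(1, length(z)))
  expect_equal(fl0$flux, 0)
  fl2 <- nitrate_flux(1e-4, no3[1:2], z[1:2], c(1, 1))
  expect_true(is.na(fl2$flux))
})

test_that("EUC-relative binning centres bins on the core and excludes the mixed layer", {
  b <- bin_relative_to_euc(c(91, 98, 99, 76, 30, 29.9, 150), d_euc = 91,
                           d_ml = 20)
  expect_equal(b$k[1], 0)              # sample exactly at the core
  expect_equal(b$k[2], 0)              # within 7.5 m of the core
  expect_equal(b$k[3], 1)
  expect_equal(b$k[4], -1)
  expect_equal(b$k[5], -4)             # at D_ML + 10: kept
  expect_true(is.na(b$k[6]))           # just above the cutoff: discarded
  expect_equal(b$bin_center[7], 60)

  # uniform field: every bin mean equals the field value
  z <- seq(35, 150, by = 1)
  b2 <- bin_relative_to_euc(z, 91, 20)
  means <- tapply(rep(7, length(z)), b2$k, mean)
  expect_true(all(means == 7))
})

test_that("diffusivity minimum sits at the core when thermocline and core align", {
  # Sep/Oct-like regime: 20 degC isotherm at the core depth
  scn <- section_scenario(n_stations = 4, euc_core_depth = 91,
                          euc_core_speed = 0.8, thermocline_depth = 91,
                          eps_deep_cycle = 1e-7, seed = 10)
  pl <- run_section_pipeline(scn, seed = 2)
  co <- pl$composite
  k0 <- which(co$bin_center == 0)
  expect_lt(co$k_rho[k0], co$k_rho[which(co$bin_center == -15)])
  expect_lt(co$k_rho[k0], co$k_rho[which(co$bin_center == 15)])
  # Sh^2 minimum at the core as well
  expect_lt(co$sh2[k0], co$sh2[which(co$bin_center == -15)])
})
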