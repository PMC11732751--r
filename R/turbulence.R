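#' Nasmyth universal shear spectrum
#'
#' One-sided wavenumber spectrum of microstructure shear for fully developed
#' isotropic turbulence, in the standard rational parameterization of the
#' non-dimensional form (Lueck's fit):
#' \deqn{G_2(x) = \frac{8.05\,x^{1/3}}{1 + (20.6\,x)^{3.715}},\qquad
#'   \Phi(k) = \varepsilon^{3/4}\nu^{-1/4}\, G_2(k/k_s),\quad
#'   k_s = (\varepsilon/\nu^3)^{1/4}\ \mathrm{cpm}.}
#' The fit integrates to 0.1334456, within 0.1 % of the isotropy value 2/15,
#' so the total shear variance satisfies
#' \eqn{\int\Phi\,dk = \varepsilon/(7.5\nu)} to the same accuracy.
#'
#' @param epsilon dissipation rate, W/kg
#' @param nu kinematic viscosity, m^2/s
#' @param k wavenumber array, cycles per metre (cpm)
#' @return spectral density of shear, (1/s)^2 per cpm
#' @export
nasmyth_spectrum <- function(epsilon, nu, k) {
  stopifnot(epsilon > 0, nu > 0, all(k >= 0))
  ks <- (epsilon / nu^3)^0.25
  epsilon^0.75 * nu^-0.25 * nasmyth_g2(k / ks)
}

nasmyth_g2 <- function(x) {
  8.05 * x^(1 / 3) / (1 + (20.6 * x)^3.715)
}

# integral of the G2 fit over (0, Inf); computed once by quadrature
.nasmyth_total <- 0.1334456

#' Fraction of shear variance resolved in a wavenumber band
#'
#' \eqn{\int_{k_1}^{k_2}\Phi\,dk / \int_0^\infty \Phi\,dk} at a given
#' epsilon and viscosity; used to correct band-limited variance integrals
#' for unresolved variance.
#'
#' @param band length-2 wavenumber interval, cpm
#' @inheritParams nasmyth_spectrum
#' @return fraction in (0, 1)
#' @export
nasmyth_fraction <- function(band, epsilon, nu) {
  ks <- (epsilon / nu^3)^0.25
  x1 <- band[1] / ks
  x2 <- band[2] / ks
  stats::integrate(nasmyth_g2, x1, x2, rel.tol = 1e-8)$value / .nasmyth_total
}

#' Microstructure shear record container
#'
#' @param shear shear time series, 1/s
#' @param sample_rate sampling rate, Hz
#' @param fall_speed profiler fall speed, m/s (0.5--0.6 typical); under
#'   Taylor's frozen-turbulence hypothesis wavenumber = frequency/fall_speed
#' @param temperature in-situ temperature, degC (sets the viscosity)
#' @param depth nominal depth of the record segment, m
#' @return object of class `shear_record`
#' @export
shear_record <- function(shear, sample_rate, fall_speed, temperature = 20,
                         depth = NA_real_) {
  if (fall_speed <= 0.1) stop("fall_speed must exceed 0.1 m/s")
  if (mean(is.finite(shear)) < 0.9) {
    stop("more than 10 % of shear samples are invalid")
  }
  structure(list(shear = as.numeric(shear), sample_rate = sample_rate,
                 fall_speed = fall_speed, temperature = temperature,
                 depth = depth), class = "shear_record")
}

# One-sided PSD of a linearly detrended, Hann-windowed segment.
# Returns frequency axis (Hz, excluding 0 and Nyquist) and density; the
# window loss is compensated by mean(w^2) so that the integral of the PSD
# estimates the variance of the detrended segment.
segment_psd <- function(x, sample_rate) {
  n <- length(x)
  tt <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))   # Hann
  xf <- stats::fft(x * w) / n
  df <- sample_rate / n
  j <- 2:(floor(n / 2))                                       # drop DC, Nyquist
  psd <- 2 * Mod(xf[j])^2 / (df * mean(w^2))
  list(freq = (j - 1) * df, psd = psd, df = df)
}

#' Dissipation rate from one shear segment
#'
#' Estimates epsilon by band-limited integration of the wavenumber shear
#' spectrum under the isotropy relation \eqn{\varepsilon = 7.5\nu\langle
#' u_z'^2\rangle}, with iterative correction for variance outside the band
#' using the Nasmyth form:
#' \enumerate{
#'   \item periodogram of the linearly detrended, Hann-windowed segment;
#'   \item partial shear variance = integral of the wavenumber spectrum over
#'     `band` (frequency mapped to wavenumber by the fall speed);
#'   \item \eqn{\varepsilon \leftarrow 7.5\nu\cdot\mathrm{variance} /
#'     f(\varepsilon)} where f is the Nasmyth band fraction at the current
#'     estimate, iterated to < 1 % relative change (max 20 iterations).
#' }
#' Estimates whose final band fraction is below 5 % are undefined
#' ("saturated"); segments whose observed variance in the control band just
#' above `band` exceeds the Nasmyth prediction by more than `noise_factor`
#' are flagged "noise" (the spectrum is not shear-like, e.g. instrument
#' noise floor).
#'
#' @param record a [shear_record()] (a single 2-s segment)
#' @param band integration band, cpm (default 2--30)
#' @param nu kinematic viscosity, m^2/s; default from the record temperature
#' @param noise_factor control-band excess ratio above which the segment is
#'   flagged as noise-dominated
#' @return list with `epsilon` (W/kg or NA), `flag` ("ok", "not_converged",
#'   "saturated", "noise"), `fraction` (resolved fraction at the returned
#'   estimate)
#' @export
epsilon_from_segment <- function(record, band = c(2, 30), nu = NULL,
                                 noise_factor = 3) {
  if (is.null(nu)) nu <- sw_viscosity(record$temperature)
  W <- record$fall_speed
  sp <- segment_psd(record$shear, record$sample_rate)
  k <- sp$freq / W                       # cpm
  phi_k <- sp$psd * W                    # (1/s)^2 / cpm
  dk <- sp$df / W
  in_band <- k >= band[1] & k <= band[2]
  if (!any(in_band)) stop("resolved wavenumbers do not cover the band")
  pv <- sum(phi_k[in_band]) * dk
  eps <- 7.5 * nu * pv                   # first guess: band fully resolved
  flag <- "not_converged"
  frac <- 1
  for (it in seq_len(20)) {
    frac <- nasmyth_fraction(band, eps, nu)
    if (frac < 0.05) {
      return(list(epsilon = NA_real_, flag = "saturated", fraction = frac))
    }
    eps_new <- 7.5 * nu * pv / frac
    if (abs(eps_new - eps) / eps < 0.01) {
      eps <- eps_new
      flag <- "ok"
      break
    }
    eps <- eps_new
  }
  # noise control band just above the integration band
  ctrl <- k > band[2] & k <= 1.5 * band[2]
  if (any(ctrl)) {
    obs <- sum(phi_k[ctrl]) * dk
    pred <- sum(nasmyth_spectrum(eps, nu, k[ctrl])) * dk
    if (pred > 0 && obs / pred > noise_factor) flag <- "noise"
  }
  list(epsilon = eps, flag = flag, fraction = frac)
}

#' Dissipation rate over a full shear record
#'
#' Splits a record into overlapping segments (default 2 s, 50 % overlap),
#' estimates epsilon per segment with [epsilon_from_segment()] and returns
#' the per-segment estimates plus their mean over unflagged segments.
#'
#' @inheritParams epsilon_from_segment
#' @param record a [shear_record()] of arbitrary duration
#' @param segment_s segment length, s
#' @param overlap fractional overlap between consecutive segments
#' @return list with `epsilon` (mean over "ok" segments), `segments`
#'   (data.frame: epsilon, flag), `n_ok`
#' @export
epsilon_from_record <- function(record, band = c(2, 30), nu = NULL,
                                segment_s = 2, overlap = 0.5,
                                noise_factor = 3) {
  n_seg <- round(segment_s * record$sample_rate)
  step <- max(1, round(n_seg * (1 - overlap)))
  starts <- seq(1, length(record$shear) - n_seg + 1, by = step)
  res <- lapply(starts, function(s) {
    seg <- record$shear[s:(s + n_seg - 1)]
    r <- record
    r$shear <- seg
    epsilon_from_segment(r, band = band, nu = nu, noise_factor = noise_factor)
  })
  segs <- data.frame(epsilon = vapply(res, `[[`, numeric(1), "epsilon"),
                     flag = vapply(res, `[[`, character(1), "flag"))
  ok <- segs$flag == "ok" & is.finite(segs$epsilon)
  list(epsilon = if (any(ok)) mean(segs$epsilon[ok]) else NA_real_,
       segments = segs, n_ok = sum(ok))
}

#' Depth-binned dissipation profile
#'
#' Arithmetic mean of segment epsilon estimates per depth bin, with
#' percentile-bootstrap 95 % confidence limits. Bins with fewer than 5
#' segments report the mean without confidence limits.
#'
#' @param epsilon segment dissipation estimates, W/kg
#' @param depth segment depths, m
#' @param breaks depth-bin edges, m (default 10-m bins spanning the data)
#' @param reps bootstrap replicates
#' @param seed RNG seed for the bootstrap
#' @return object of class `epsilon_profile`: data.frame with `depth` (bin
#'   centre), `epsilon`, `lower`, `upper`, `n`
#' @export
profile_epsilon <- function(epsilon, depth, breaks = NULL, reps = 2000,
                            seed = NULL) {
  ok <- is.finite(epsilon) & is.finite(depth)
  epsilon <- epsilon[ok]; depth <- depth[ok]
  if (is.null(breaks)) {
    breaks <- seq(floor(min(depth) / 10) * 10,
                  ceiling(max(depth) / 10) * 10, by = 10)
  }
  bin <- cut(depth, breaks, include.lowest = TRUE, labels = FALSE)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(depth = centres, epsilon = NA_real_,
                    lower = NA_real_, upper = NA_real_, n = 0L)
  for (b in sort(unique(bin))) {
    v <- epsilon[bin == b]
    out$epsilon[b] <- mean(v)
    out$n[b] <- length(v)
    if (length(v) >= 5) {
      ci <- bootstrap_mean_ci(v, reps = reps, seed = seed)
      out$lower[b] <- ci[1]; out$upper[b] <- ci[2]
    }
  }
  class(out) <- c("epsilon_profile", "data.frame")
  out
}

#' Osborn diapycnal diffusivity
#'
#' K_rho = Gamma * epsilon / N^2 with mixing efficiency Gamma = 0.2 by
#' default. Undefined where N^2 <= 0: the mixing efficiency is not
#' well-defined in unstratified or unstable water.
#'
#' @param epsilon dissipation rate, W/kg (> 0 where defined)
#' @param n2 squared buoyancy frequency, 1/s^2
#' @param gamma mixing efficiency (dimensionless)
#' @return diapycnal diffusivity, m^2/s (NA where undefined)
#' @export
diffusivity <- function(epsilon, n2, gamma = 0.2) {
  stopifnot(gamma > 0)
  k <- gamma * epsilon / n2
  k[!is.finite(n2) | n2 <= 0] <- NA_real_
  k[is.finite(epsilon) & epsilon <= 0] <- NA_real_
  k
}

#' Upward diffusive nitrate flux
#'
#' F_NO3 = K_rho * dNO3/dz per depth bin, with the gradient taken as the
#' least-squares slope of nitrate on depth within each bin (>= 3 samples
#' required). Depth is positive down, so a positive slope means nitrate
#' increasing downward and the flux is upward-positive. Native flux units
#' are umol/kg m/s; multiplying by an in-situ density converts to
#' mmol/m^2/s.
#'
#' @param k_rho diapycnal diffusivity per bin, m^2/s
#' @param no3 nitrate samples, umol/kg
#' @param depth depths of the nitrate samples, m
#' @param bin per-sample bin assignment (same bin labels as `k_rho` names
#'   or indices 1..length(k_rho))
#' @param rho optional density, kg/m^3; when given the flux is also returned
#'   in mmol/m^2/s (`flux_mmol_m2_s`)
#' @return data.frame with `bin`, `k_rho`, `gradient` (umol/kg per m),
#'   `flux` (umol/kg m/s) and optionally `flux_mmol_m2_s`
#' @export
nitrate_flux <- function(k_rho, no3, depth, bin, rho = NULL) {
  bins <- seq_along(k_rho)
  grad <- vapply(bins, function(b) {
    sel <- bin == b & is.finite(no3) & is.finite(depth)
    if (sum(sel, na.rm = TRUE) < 3) return(NA_real_)
    ls_slope(depth[sel], no3[sel])
  }, numeric(1))
  flux <- k_rho * grad
  out <- data.frame(bin = bins, k_rho = k_rho, gradient = grad, flux = flux)
  if (!is.null(rho)) out$flux_mmol_m2_s <- flux * rho / 1000
  out
}

#' Bin samples relative to the EUC core depth
#'
#' Assigns samples to `bin_width`-m bins (default 15 m) centred at
#' D_EUC + k * bin_width, k integer, after discarding all samples shallower
#' than D_ML + `exclude_below_ml` (default 10 m below the mixed layer, where
#' the mixing efficiency is ill-defined).
#'
#' @param depth sample depths, m
#' @param d_euc EUC core depth, m
#' @param d_ml mixed layer depth, m
#' @param bin_width bin width, m
#' @param exclude_below_ml exclusion buffer below the mixed layer, m
#' @return data.frame with `depth`, `rel_depth` (depth - D_EUC), `k` (bin
#'   index, NA for discarded samples), `bin_center` (relative, m)
#' @export
bin_relative_to_euc <- function(depth, d_euc, d_ml, bin_width = 15,
                                exclude_below_ml = 10) {
  stopifnot(is.finite(d_euc), is.finite(d_ml))
  rel <- depth - d_euc
  k <- round(rel / bin_width)
  keep <- depth >= d_ml + exclude_below_ml
  k[!keep] <- NA_integer_
  data.frame(depth = depth, rel_depth = rel, k = k,
             bin_center = k * bin_width)
}
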