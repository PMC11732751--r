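#' End-to-end section pipeline
#'
#' Runs the full cruise-section analysis on a synthetic scenario: generate
#' the section, detect per-station mixed-layer depth, 20 degC isotherm and
#' EUC core, synthesize and process microstructure shear records at regular
#' depths (Nasmyth band-integration estimator), bin everything in 15-m bins
#' relative to the EUC core (discarding the mixed layer plus 10 m), and
#' form along-section composites of u, Sh^2, epsilon, K_rho, NO3 gradient
#' and upward nitrate flux with 95 % confidence limits (bootstrap for
#' epsilon, error propagation for K_rho and the flux, SE for the rest).
#'
#' @param scenario a [section_scenario()]
#' @param seed integer seed for the microstructure synthesis and bootstrap
#'   (the scenario's own seed controls the section fields)
#' @param band dissipation integration band, cpm
#' @param gamma mixing efficiency
#' @param bin_width EUC-relative bin width, m
#' @param ms_depths depths of synthetic microstructure segments, m
#' @param shear_duration,shear_rate record length (s) and sampling rate
#'   (Hz) of each synthetic shear record
#' @param out_dir optional directory; when given, station table, composites
#'   and manifest are written as CSV/JSON
#' @return object of class `section_pipeline`: list with `stations`
#'   (data.frame), `composite` (data.frame over EUC-relative bins),
#'   `truth`, `manifest`
#' @export
run_section_pipeline <- function(scenario, seed = 1, band = c(2, 30),
                                 gamma = 0.2, bin_width = 15,
                                 ms_depths = seq(15, 185, by = 10),
                                 shear_duration = 20, shear_rate = 128,
                                 out_dir = NULL) {
  stopifnot(inherits(scenario, "section_scenario"))
  if (scenario$n_stations < 1) stop("scenario has no stations")
  stopifnot(gamma > 0, bin_width > 0)
  sec <- make_section(scenario)
  ns <- scenario$n_stations
  vel <- sec$velocity

  stations <- data.frame(station = seq_len(ns), lon = sec$truth$lon,
                         d_ml = NA_real_, d_20 = NA_real_,
                         d_euc = NA_real_, core_speed = NA_real_,
                         euc_flag = NA_character_)
  seg_rows <- list()
  ctd_rows <- list()
  sh <- shear_squared(vel)

  for (j in seq_len(ns)) {
    p <- sec$profiles[[j]]
    dml <- mixed_layer_depth(p)$depth
    d20 <- isotherm_depth(p, below = if (is.finite(dml)) dml else 0)$depth
    core <- euc_core(vel$depth, vel$u[, j])
    stations$d_ml[j] <- dml
    stations$d_20[j] <- d20
    stations$d_euc[j] <- core$depth
    stations$core_speed[j] <- core$speed
    stations$euc_flag[j] <- core$flag
    if (!is.finite(dml) || !is.finite(core$depth)) next

    n2 <- buoyancy_frequency_squared(p)

    # synthetic microstructure: one record per depth, processed by the
    # spectral estimator
    eps_hat <- rep(NA_real_, length(ms_depths))
    for (i in seq_along(ms_depths)) {
      z <- ms_depths[i]
      rec_seed <- (seed * 7919 + j * 211 + i) %% 2147483647
      t_local <- stats::approx(p$depth, p$temperature, z,
                               ties = "ordered")$y
      rec <- make_shear_record(sec$truth$eps(z, j),
                               nu = sw_viscosity(t_local),
                               duration = shear_duration,
                               sample_rate = shear_rate, seed = rec_seed,
                               temperature = t_local, depth = z)
      eps_hat[i] <- epsilon_from_record(rec, band = band)$epsilon
    }
    ba <- bin_relative_to_euc(ms_depths, core$depth, dml,
                              bin_width = bin_width)
    seg_rows[[j]] <- data.frame(station = j, depth = ms_depths,
                                k = ba$k, epsilon = eps_hat)

    # CTD-side quantities on the same relative bins
    bc <- bin_relative_to_euc(p$depth, core$depth, dml,
                              bin_width = bin_width)
    ctd_rows[[j]] <- data.frame(
      station = j, depth = p$depth, k = bc$k,
      n2 = n2, no3 = if (is.null(p$nitrate)) NA_real_ else p$nitrate,
      u = stats::approx(vel$depth, vel$u[, j], p$depth, ties = "ordered")$y,
      sh2 = sh$sh2[match(round(p$depth), sh$depth), j])
  }
  segs <- do.call(rbind, seg_rows)
  ctd <- do.call(rbind, ctd_rows)
  if (is.null(segs) || all(!is.finite(segs$epsilon))) {
    stop("no usable stations in the section")
  }

  ks <- sort(unique(stats::na.omit(segs$k)))
  comp <- data.frame(k = ks, bin_center = ks * bin_width)
  nn <- length(ks)
  comp$u <- comp$u_se <- comp$sh2 <- comp$sh2_se <- comp$epsilon <-
    comp$eps_lower <- comp$eps_upper <- comp$n2 <- comp$n2_se <-
    comp$k_rho <- comp$k_rho_se <- comp$no3 <- comp$gradient <-
    comp$gradient_se <- comp$flux <- comp$flux_se <- rep(NA_real_, nn)
  comp$n_eps <- 0L
  for (r in seq_len(nn)) {
    k <- ks[r]
    e <- segs$epsilon[segs$k %in% k & is.finite(segs$epsilon)]
    cc <- ctd[ctd$k %in% k, ]
    comp$n_eps[r] <- length(e)
    if (length(e) > 0) comp$epsilon[r] <- mean(e)
    if (length(e) >= 5) {
      ci <- bootstrap_mean_ci(e, seed = (seed * 31 + k + 1000) %% 2147483647)
      comp$eps_lower[r] <- ci[1]; comp$eps_upper[r] <- ci[2]
    }
    # per-station means are the independent samples for u, sh2, n2, no3
    st_mean <- function(v) {
      m <- tapply(v, cc$station, mean, na.rm = TRUE)
      m[is.finite(m)]
    }
    for (nm in c("u", "sh2", "n2", "no3")) {
      m <- st_mean(cc[[nm]])
      if (length(m) >= 2) {
        comp[[nm]][r] <- mean(m)
        comp[[paste0(nm, "_se")]][r] <- standard_error(m)
      } else if (length(m) == 1) comp[[nm]][r] <- m
    }
    # nitrate gradient: pooled in-bin regression slope on relative depth
    okg <- is.finite(cc$no3)
    if (sum(okg) >= 3) {
      comp$gradient[r] <- ls_slope(cc$depth[okg], cc$no3[okg])
      # slope SE from the pooled regression
      x <- cc$depth[okg]; y <- cc$no3[okg]
      res <- y - mean(y) - comp$gradient[r] * (x - mean(x))
      sxx <- sum((x - mean(x))^2)
      if (length(x) > 2 && sxx > 0) {
        comp$gradient_se[r] <- sqrt(sum(res^2) / (length(x) - 2) / sxx)
      }
    }
    # K_rho and flux with propagated uncertainties
    if (is.finite(comp$epsilon[r]) && is.finite(comp$n2[r]) &&
        comp$n2[r] > 0) {
      comp$k_rho[r] <- diffusivity(comp$epsilon[r], comp$n2[r], gamma)
      eps_se <- if (is.finite(comp$eps_upper[r])) {
        (comp$eps_upper[r] - comp$eps_lower[r]) / (2 * 1.96)
      } else NA_real_
      rel <- sqrt((eps_se / comp$epsilon[r])^2 +
                    (comp$n2_se[r] / comp$n2[r])^2)
      comp$k_rho_se[r] <- abs(comp$k_rho[r]) * rel
      if (is.finite(comp$gradient[r])) {
        comp$flux[r] <- comp$k_rho[r] * comp$gradient[r]
        relf <- sqrt(rel^2 + (comp$gradient_se[r] / comp$gradient[r])^2)
        comp$flux_se[r] <- abs(comp$flux[r]) * relf
      }
    }
  }

  config <- list(scenario_seed = scenario$seed, band = band, gamma = gamma,
                 bin_width = bin_width, ms_depths = ms_depths,
                 shear_duration = shear_duration, shear_rate = shear_rate)
  out <- structure(list(stations = stations, composite = comp,
                        segments = segs, truth = sec$truth,
                        manifest = run_manifest(config, seed)),
                   class = "section_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stations, file.path(out_dir, "stations.csv"),
                     row.names = FALSE)
    utils::write.csv(comp, file.path(out_dir, "composite.csv"),
                     row.names = FALSE)
    write_profiles_csv(sec$profiles, file.path(out_dir, "profiles.csv"))
    write_velocity_csv(sec$velocity, file.path(out_dir, "velocity.csv"))
    write_truth_json(out$manifest, file.path(out_dir, "manifest.json"))
  }
  out
}

#' @export
print.section_pipeline <- function(x, ...) {
  cat(sprintf(
    "<section_pipeline> %d stations; mean core %.1f m at %.2f m/s; %d EUC-relative bins\n",
    nrow(x$stations), mean(x$stations$d_euc, na.rm = TRUE),
    mean(x$stations$core_speed, na.rm = TRUE), nrow(x$composite)))
  invisible(x)
}

#' End-to-end mooring pipeline
#'
#' Builds the seasonal-climatology bundle from synthetic moored records:
#' individual seasonal cycles of EUC core depth and 20 degC isotherm depth
#' and their difference (with propagated SE), a monthly climatology of a
#' moored dissipation series with a planted seasonal cycle, and the
#' Richardson-number climatology formed as the ratio of the N^2 and Sh^2
#' climatologies of 10-day-mean daily series.
#'
#' @param scenario a [mooring_scenario()]
#' @param eps_pars planted lognormal seasonal dissipation: list with
#'   `log10_mean`, `log10_amp`, `phase` (day of maximum), `sd_log10`
#'   (AR(1) noise SD in decades), `timescale` (days)
#' @param ri_pars planted N^2 and Sh^2 daily series: lists `n2` and `sh2`,
#'   each with `mean`, `amp`, `phase`, plus `noise_rel` (relative AR(1)
#'   noise SD) and `timescale`
#' @param out_dir optional output directory for CSV/JSON products
#' @return object of class `mooring_pipeline`: list with `clim_euc`,
#'   `clim_20`, `depth_diff`, `eps_monthly`, `ri_clim`, `truth`, `manifest`
#' @export
run_mooring_pipeline <- function(scenario = mooring_scenario(),
                                 eps_pars = list(log10_mean = -8,
                                                 log10_amp = 0.5,
                                                 phase = 181,
                                                 sd_log10 = 0.4,
                                                 timescale = 5),
                                 ri_pars = list(
                                   n2 = list(mean = 2e-4, amp = 0.3e-4,
                                             phase = 15),
                                   sh2 = list(mean = 4e-4, amp = 3.5e-4,
                                              phase = 181),
                                   noise_rel = 0.2, timescale = 10),
                                 out_dir = NULL) {
  stopifnot(inherits(scenario, "mooring_scenario"))
  moor <- make_mooring(scenario)
  clim_euc <- mooring_seasonal_cycle(moor$time, moor$d_euc,
                                     cadence = scenario$cadence)
  clim_20 <- mooring_seasonal_cycle(moor$time, moor$d_20,
                                    cadence = scenario$cadence)
  dd <- depth_difference_cycle(clim_euc, clim_20)

  n <- length(moor$time)
  harm <- function(doy, mean, amp, phase) {
    mean + amp * cos(2 * pi * (doy - phase) / 365)
  }
  eps_series <- with_seed(scenario$seed + 101, {
    10^(harm(moor$doy, eps_pars$log10_mean, eps_pars$log10_amp,
             eps_pars$phase) +
          ar1_series(n, eps_pars$sd_log10, eps_pars$timescale,
                     scenario$cadence))
  })
  eps_monthly <- monthly_epsilon_climatology(moor$time, eps_series,
                                             seed = scenario$seed + 7)

  mk_clim <- function(pars, sub_seed) {
    series <- with_seed(scenario$seed + sub_seed, {
      base <- harm(moor$doy, pars$mean, pars$amp, pars$phase)
      base * (1 + ar1_series(n, ri_pars$noise_rel, ri_pars$timescale,
                             scenario$cadence))
    })
    tm <- ten_day_mean(series)
    t10 <- (seq_along(tm) - 0.5) * 10
    mooring_seasonal_cycle(t10, tm, cadence = 10)
  }
  clim_n2 <- mk_clim(ri_pars$n2, 202)
  clim_sh2 <- mk_clim(ri_pars$sh2, 303)
  ri <- ri_climatology(clim_n2, clim_sh2)

  config <- list(scenario = unclass(scenario)[c("duration_days", "cadence",
                                                "noise_sd", "timescale",
                                                "seed")],
                 eps_pars = eps_pars, ri_pars = ri_pars)
  out <- structure(list(clim_euc = clim_euc, clim_20 = clim_20,
                        depth_diff = dd, eps_monthly = eps_monthly,
                        clim_n2 = clim_n2, clim_sh2 = clim_sh2,
                        ri_clim = ri,
                        truth = c(moor$truth, list(eps = eps_pars,
                                                   ri = ri_pars)),
                        manifest = run_manifest(config, scenario$seed)),
                   class = "mooring_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_climatology_csv(dd, file.path(out_dir, "depth_difference.csv"))
    write_climatology_csv(ri, file.path(out_dir, "richardson.csv"))
    utils::write.csv(eps_monthly, file.path(out_dir, "epsilon_monthly.csv"),
                     row.names = FALSE)
    write_truth_json(out$manifest, file.path(out_dir, "manifest.json"))
  }
  out
}

#' @export
print.mooring_pipeline <- function(x, ...) {
  pk <- x$depth_diff$phase[which.max(x$depth_diff$value)]
  cat(sprintf(
    "<mooring_pipeline> depth difference peaks at day %d (%.1f m); %d Ri entries\n",
    pk, max(x$depth_diff$value, na.rm = TRUE), nrow(x$ri_clim)))
  invisible(x)
}
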