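# Seeded generators for stratified CTD casts, bacterial-layer seasons,
# flow-cytometry event clouds and warm-season weather, with ground truth.

#' Scenario for a two-layer stratified lake cast
#'
#' Describes the physical structure a generated cast emulates: warm, dilute,
#' oxygenated mixolimnion over a cold, ion-rich, anoxic monimolimnion, with
#' logistic (sigmoid) transitions across the chemocline, a Gaussian
#' turbidity peak marking the bacterial layer in the lower chemocline, and
#' sigmoidal oxygen decay to zero. Defaults describe a mid-summer alpine
#' meromictic basin: 15 degree surface water, 4 degree bottom water, k20
#' rising from ~150 to ~400 uS/cm across a chemocline near 11 m, a 24-FTU
#' layer peak at 13 m, and 8 mg/l of surface oxygen vanishing below ~10 m.
#' These are scenario defaults for testing, not measured lake facts.
#'
#' @param t_surface,t_bottom Surface/bottom temperature, degrees C.
#' @param k20_surface,k20_bottom Surface/bottom normalised conductivity,
#'   uS/cm.
#' @param chemocline_depth,chemocline_width Centre and logistic width of the
#'   chemocline transition, metres.
#' @param bl_center,bl_halfwidth_sigma Centre and Gaussian sigma of the
#'   bacterial-layer turbidity peak, metres.
#' @param bl_peak_ftu Turbidity peak amplitude above the 1 FTU baseline.
#' @param do_surface Surface dissolved oxygen, mg/l.
#' @param do_cline_depth,do_cline_width Centre and width of the oxygen
#'   decay sigmoid, metres.
#' @param z_bot Cast bottom depth, metres.
#' @param noise_sd Named list of per-channel Gaussian noise standard
#'   deviations (`temp`, `cond`, `do`, `turb`); zero by default so analytic
#'   recoveries are exact.
#' @return A list of class `lake_scenario`.
#' @export
lake_scenario <- function(t_surface = 15, t_bottom = 4,
                          k20_surface = 150, k20_bottom = 400,
                          chemocline_depth = 11, chemocline_width = 0.8,
                          bl_center = 13, bl_halfwidth_sigma = 0.5,
                          bl_peak_ftu = 24, do_surface = 8,
                          do_cline_depth = 10, do_cline_width = 0.5,
                          z_bot = 21,
                          noise_sd = list(temp = 0, cond = 0,
                                          do = 0, turb = 0)) {
  stopifnot(t_surface >= t_bottom, k20_bottom >= k20_surface,
            bl_center > chemocline_depth,
            chemocline_width > 0, bl_halfwidth_sigma > 0, do_cline_width > 0)
  structure(as.list(environment()), class = "lake_scenario")
}

#' Generate one synthetic CTD cast
#'
#' Deterministic for a fixed seed. The channel models are:
#' temperature `T(z) = t_bottom + (t_surface - t_bottom) *
#' plogis((chemocline_depth - z) / chemocline_width)`; k20 the mirrored
#' sigmoid between its own endpoints; dissolved oxygen
#' `do_surface * plogis((do_cline_depth - z) / do_cline_width)`; turbidity
#' `1 + bl_peak_ftu * exp(-(z - bl_center)^2 / (2 sigma^2))`. Raw
#' conductivity is back-computed from k20 through the linear temperature
#' compensation so the normalisation step can be exercised downstream.
#' Gaussian noise per channel is added last; oxygen and turbidity are
#' clamped at zero.
#'
#' @param scenario A [lake_scenario()].
#' @param grid_step Depth grid spacing, metres (default 0.1).
#' @param seed Integer RNG seed.
#' @param cast_id,timestamp Cast metadata.
#' @return A `ctd_profile`.
#' @export
gen_ctd_profile <- function(scenario = lake_scenario(), grid_step = 0.1,
                            seed = 1, cast_id = "synth",
                            timestamp = as.POSIXct("2020-07-15 10:00:00",
                                                   tz = "UTC")) {
  s <- scenario
  z <- seq(0, s$z_bot, by = grid_step)
  temp <- s$t_bottom + (s$t_surface - s$t_bottom) *
    stats::plogis((s$chemocline_depth - z) / s$chemocline_width)
  k20 <- s$k20_surface + (s$k20_bottom - s$k20_surface) *
    stats::plogis((z - s$chemocline_depth) / s$chemocline_width)
  do <- s$do_surface * stats::plogis((s$do_cline_depth - z) / s$do_cline_width)
  turb <- 1 + s$bl_peak_ftu *
    exp(-(z - s$bl_center)^2 / (2 * s$bl_halfwidth_sigma^2))
  bga <- 3 * exp(-(z - (s$bl_center - 1.5))^2 / (2 * 0.6^2))

  ns <- s$noise_sd
  withr::with_seed(seed, {
    temp <- temp + stats::rnorm(length(z), sd = ns$temp %||% 0)
    k20 <- k20 + stats::rnorm(length(z), sd = ns$cond %||% 0)
    do <- pmax(0, do + stats::rnorm(length(z), sd = ns$do %||% 0))
    turb <- pmax(0, turb + stats::rnorm(length(z), sd = ns$turb %||% 0))
  })
  cond_raw <- k20 * (1 + 0.020 * (temp - 20))

  ctd_profile(depth_m = z, temp_c = temp,
              cond_raw_uScm = cond_raw, k20_uScm = k20,
              do_mgL = do, turb_ftu = turb, bgapc_ppb = bga,
              cast_id = cast_id, timestamp = timestamp,
              z_bot_max = s$z_bot)
}

#' Scenario for a season of casts with a drifting bacterial layer
#'
#' The layer centre and Gaussian width follow linear trajectories across
#' the season — the canonical seasonal pattern of a gradually sinking,
#' thinning layer.
#'
#' @param n_casts Number of casts (>= 1).
#' @param start_date,end_date Season span.
#' @param bl_center_start Layer centre at the first cast, metres.
#' @param bl_center_drift Total downward drift across the season, metres.
#' @param bl_sigma_start,bl_sigma_end Gaussian sigma at season start/end.
#' @param base A [lake_scenario()] supplying everything else.
#' @param seed Integer RNG seed.
#' @return A list of class `season_scenario`.
#' @export
season_scenario <- function(n_casts = 10,
                            start_date = as.Date("2020-06-15"),
                            end_date = as.Date("2020-10-01"),
                            bl_center_start = 12.5, bl_center_drift = 1.5,
                            bl_sigma_start = 0.5, bl_sigma_end = 0.35,
                            base = lake_scenario(), seed = 1) {
  stopifnot(n_casts >= 1)
  centers <- bl_center_start +
    bl_center_drift * seq(0, 1, length.out = max(n_casts, 2))[seq_len(n_casts)]
  if (any(centers <= base$chemocline_depth) || any(centers >= base$z_bot)) {
    rlang::abort("Layer trajectory exits the water column.",
                 class = "meromix_error_scenario")
  }
  structure(as.list(environment()), class = "season_scenario")
}

#' Generate a season of casts with per-cast ground truth
#'
#' @param scenario A [season_scenario()].
#' @return A list with `profiles` (list of `ctd_profile`) and `truth`
#'   (tibble: `cast_id`, `date`, `bl_center_m`, `bl_sigma_m`, and the
#'   analytic threshold crossings `top_m`, `bottom_m`, `thickness_m` for a
#'   10 FTU threshold on the noise-free peak).
#' @export
gen_season <- function(scenario = season_scenario()) {
  s <- scenario
  dates <- seq(s$start_date, s$end_date, length.out = s$n_casts)
  sigmas <- seq(s$bl_sigma_start, s$bl_sigma_end, length.out = s$n_casts)
  centers <- s$centers

  out <- purrr::map(seq_len(s$n_casts), function(i) {
    sc <- s$base
    sc$bl_center <- centers[i]
    sc$bl_halfwidth_sigma <- sigmas[i]
    gen_ctd_profile(sc, seed = s$seed + i,
                    cast_id = sprintf("synth_%02d", i),
                    timestamp = as.POSIXct(dates[i], tz = "UTC"))
  })
  # analytic > 10 FTU crossings of baseline 1 + peak * gaussian
  half <- sqrt(2 * sigmas^2 * log(s$base$bl_peak_ftu / (10 - 1)))
  truth <- tibble::tibble(
    cast_id = sprintf("synth_%02d", seq_len(s$n_casts)),
    date = as.Date(dates),
    bl_center_m = centers,
    bl_sigma_m = sigmas,
    top_m = centers - half,
    bottom_m = centers + half,
    thickness_m = 2 * half)
  list(profiles = out, truth = truth)
}

#' Generate a synthetic flow-cytometry event cloud
#'
#' Draws `n` events from three log-normal phenotype clusters plus debris.
#' Cluster log10(FSC-A) means follow the cell-size ordering of the three
#' phototroph phenotypes (GSB smallest, large-celled PSB largest); FSC-H is
#' tied to FSC-A with a fixed ratio; FL3-A is drawn per cluster well above
#' the red-fluorescence threshold. Debris is drawn uniformly *below both*
#' acquisition thresholds, so threshold-retention tests have exact
#' expectations. Events are allocated multinomially and true labels are
#' kept in `phenotype_true`.
#'
#' @param fractions Named proportions for `gsb`, `small_psb`, `large_psb`
#'   (need not include debris).
#' @param n Total number of events.
#' @param cluster_means log10(FSC-A) means per phenotype (defaults 4, 5, 6).
#' @param cluster_sd log10-space standard deviation (default 0.1).
#' @param debris_fraction Proportion of sub-threshold debris; fractions
#'   plus debris must sum to 1.
#' @param volume_ml Acquired volume, ml.
#' @param sample_label Position label for the table.
#' @param seed Integer RNG seed.
#' @return A `fcm_events` tibble with a `phenotype_true` column.
#' @export
gen_fcm_events <- function(fractions = c(gsb = 1 / 3, small_psb = 1 / 3,
                                         large_psb = 1 / 3),
                           n = 10000,
                           cluster_means = c(gsb = 4.0, small_psb = 5.0,
                                             large_psb = 6.0),
                           cluster_sd = 0.1,
                           debris_fraction = 0, volume_ml = 0.05,
                           sample_label = "sample", seed = 1) {
  p <- c(fractions, debris = debris_fraction)
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    rlang::abort("fractions plus debris_fraction must form a simplex.",
                 class = "meromix_error_parameter")
  }
  if (n == 0) {
    return(fcm_events(tibble::tibble(fsc_h = double(), fsc_a = double(),
                                     fl1_a = double(), fl2_a = double(),
                                     fl3_a = double(), fl4_a = double(),
                                     phenotype_true = character()),
                      volume_ml = volume_ml, sample_label = sample_label))
  }
  fl3_means <- c(gsb = 3.6, small_psb = 4.0, large_psb = 4.4)
  withr::with_seed(seed, {
    lab <- sample(names(p), size = n, replace = TRUE, prob = p)
    is_debris <- lab == "debris"
    lg_fsc <- numeric(n)
    lg_fl3 <- numeric(n)
    for (ph in names(fractions)) {
      k <- lab == ph
      lg_fsc[k] <- stats::rnorm(sum(k), cluster_means[[ph]], cluster_sd)
      lg_fl3[k] <- stats::rnorm(sum(k), fl3_means[[ph]], cluster_sd)
    }
    fsc_a <- 10^lg_fsc
    fsc_h <- 0.8 * fsc_a
    fl3_a <- 10^lg_fl3
    # debris strictly below both acquisition thresholds
    fsc_h[is_debris] <- stats::runif(sum(is_debris), 50, 1999)
    fsc_a[is_debris] <- fsc_h[is_debris] / 0.8
    fl3_a[is_debris] <- stats::runif(sum(is_debris), 0, 1099)
    fl1 <- stats::runif(n, 100, 1000)
    fl2 <- stats::runif(n, 100, 1000)
    fl4 <- stats::runif(n, 100, 1000)
  })
  fcm_events(tibble::tibble(fsc_h = fsc_h, fsc_a = fsc_a,
                            fl1_a = fl1, fl2_a = fl2, fl3_a = fl3_a,
                            fl4_a = fl4, phenotype_true = lab),
             volume_ml = volume_ml, sample_label = sample_label)
}

#' Generate a synthetic meteorological series
#'
#' Temperature is a seasonal sinusoid plus a linear interannual trend plus
#' first-order autocorrelated noise; rainfall arrives as Poisson-thinned
#' storm days with gamma-distributed depths spread over the day; net
#' radiation follows a clear-sky diurnal/seasonal cycle damped on rain
#' days. Deterministic per seed.
#'
#' @param days Number of days (>= 1).
#' @param start Start date.
#' @param mean_temp_c Long-term mean temperature, degrees C.
#' @param seasonal_amplitude_c Amplitude of the annual cycle, degrees C.
#' @param trend_c_per_year Linear warming trend (default 0.0325).
#' @param noise_sd Innovation sd of the AR(1) noise, degrees C.
#' @param ar1 AR(1) coefficient of the noise.
#' @param storm_rate Expected storm days per day (default 0.15).
#' @param cadence_s Record interval in seconds (default 600, the native
#'   10-minute station cadence; use 86400 for cheap long series).
#' @param seed Integer RNG seed.
#' @return A `meteo_series` tibble.
#' @export
gen_meteo <- function(days, start = as.Date("1990-01-01"),
                      mean_temp_c = 5, seasonal_amplitude_c = 8,
                      trend_c_per_year = 0.0325, noise_sd = 1,
                      ar1 = 0.9, storm_rate = 0.15,
                      cadence_s = 600, seed = 1) {
  stopifnot(days >= 1, cadence_s > 0)
  per_day <- max(1L, as.integer(round(86400 / cadence_s)))
  n <- days * per_day
  ts <- as.POSIXct(start, tz = "UTC") + cadence_s * (seq_len(n) - 1)
  t_years <- (seq_len(n) - 1) * cadence_s / (365.25 * 86400)
  doy_frac <- t_years %% 1
  day_index <- rep(seq_len(days), each = per_day)

  withr::with_seed(seed, {
    eps <- stats::rnorm(n, sd = noise_sd)
    noise <- if (noise_sd > 0) as.numeric(
      stats::filter(eps, ar1, method = "recursive")) else numeric(n)
    storm_day <- stats::rpois(days, storm_rate) > 0
    depth <- ifelse(storm_day, stats::rgamma(days, shape = 2, scale = 15), 0)
  })

  temp <- mean_temp_c +
    seasonal_amplitude_c * sin(2 * pi * (doy_frac - 0.25)) +
    trend_c_per_year * t_years + noise
  # diurnal clear-sky radiation, damped to 30% on storm days
  tod <- (as.numeric(ts) %% 86400) / 86400
  rad <- pmax(0, 600 * sin(pi * (tod * 2 - 0.5))) *
    (0.6 + 0.4 * cos(2 * pi * (doy_frac - 0.5)))
  rad <- rad * ifelse(storm_day[day_index], 0.3, 1)
  rain <- depth[day_index] / per_day

  meteo_series(ts, air_temp_c = temp, net_rad_wm2 = rad, rain_mm = rain)
}

#' Generate annual mean temperatures around a known trend line
#'
#' The lightweight companion to [gen_meteo()] for Monte-Carlo trend
#' recovery: annual means are the truth line plus independent Gaussian
#' noise.
#'
#' @param years Vector of calendar years.
#' @param base_temp_c Intercept at the first year, degrees C.
#' @param trend_c_per_year True slope (default 0.0325).
#' @param noise_sd Interannual noise sd, degrees C (default 0.2).
#' @param seed Integer RNG seed.
#' @return A tibble with `year` and `temp_c`.
#' @export
gen_annual_means <- function(years = 1990:2024, base_temp_c = 5,
                             trend_c_per_year = 0.0325, noise_sd = 0.2,
                             seed = 1) {
  withr::with_seed(seed, {
    temp <- base_temp_c + trend_c_per_year * (years - years[1]) +
      stats::rnorm(length(years), sd = noise_sd)
  })
  tibble::tibble(year = years, temp_c = temp)
}
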