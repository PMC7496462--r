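#' Ecological truth parameters for the synthetic generator
#'
#' Controls the latent GPP and RECO surfaces of a synthetic site-year.
#' GPP responds to light (hyperbolic saturation with `light_half_saturation`
#' W m-2), VPD above `vpd0` (exponential downregulation), temperature
#' (Gaussian optimum), soil water (logistic ramp at
#' `swc_stress_threshold` % vol), diffuse light (LUE enhancement scaling
#' with `1 - SW_IN/SW_IN_POT`) and an afternoon depression that creates a
#' diel hysteresis loop. RECO is Lloyd-Taylor on a convex blend of air and
#' soil temperature (`ta_weight + ts_weight = 1`), modulated by phenology
#' and soil water, with an optional post-rewetting respiration pulse
#' (amplitude decaying over `pulse_decay_days` after a rain day that ends a
#' dry spell of at least `pulse_dry_days` days).
#'
#' @param lue_max maximum light-use efficiency (umol CO2 per W).
#' @param light_half_saturation half-saturation irradiance (W m-2).
#' @param vpd_sensitivity hPa-1, active above `vpd0`.
#' @param vpd0 VPD threshold (hPa, default 10).
#' @param temp_optimum,temp_width Gaussian temperature response (deg C).
#' @param swc_stress_threshold soil-water stress midpoint (% vol).
#' @param diffuse_enhancement unitless >= 0.
#' @param afternoon_depression unitless in [0, 1).
#' @param E0_true,Rref_base Lloyd-Taylor parameters of the latent RECO.
#' @param ts_weight soil-temperature weight (air weight is `1 - ts_weight`).
#' @param swc_resp_threshold soil-water midpoint of the RECO modifier.
#' @param pulse_amplitude respiration-pulse peak (umol CO2 m-2 s-1).
#' @param pulse_decay_days e-folding time of the pulse (days).
#' @param pulse_dry_days dry-spell length required to arm a pulse.
#' @param phen_peak_doy,phen_width,phen_min smooth annual phenology
#'   multiplier (Gaussian around the peak day with floor `phen_min`).
#' @return list of class `truth_params`.
#' @export
truth_params <- function(lue_max = 0.127, light_half_saturation = 400,
                         vpd_sensitivity = 0.04, vpd0 = 10,
                         temp_optimum = 22, temp_width = 14,
                         swc_stress_threshold = 14,
                         diffuse_enhancement = 0.4,
                         afternoon_depression = 0.25,
                         E0_true = 180, Rref_base = 5,
                         ts_weight = 0.5,
                         swc_resp_threshold = 12,
                         pulse_amplitude = 0, pulse_decay_days = 2,
                         pulse_dry_days = 10,
                         phen_peak_doy = 190, phen_width = 70,
                         phen_min = 0.08) {
  p <- as.list(environment())
  stopifnot(p$ts_weight >= 0, p$ts_weight <= 1,
            p$afternoon_depression >= 0, p$afternoon_depression < 1)
  class(p) <- "truth_params"
  p
}

#' Observation-noise parameters
#'
#' Heteroscedastic double-exponential (Laplace) noise, the conventional
#' error family for eddy-covariance fluxes: standard deviation
#' `sd_base + sd_slope * |NEE|`. Records are additionally dropped to
#' missing at the stated day/night fractions to emulate u*-filtering and
#' instrument gaps.
#'
#' @param sd_base base noise standard deviation (umol CO2 m-2 s-1).
#' @param sd_slope unitless scaling with flux magnitude.
#' @param missing_fraction_day,missing_fraction_night fractions in [0, 1).
#' @param family `"laplace"` (default) or `"gaussian"`.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(sd_base = 0.7, sd_slope = 0.12,
                         missing_fraction_day = 0.3,
                         missing_fraction_night = 0.5,
                         family = c("laplace", "gaussian")) {
  stopifnot(sd_base > 0, missing_fraction_day >= 0,
            missing_fraction_day < 1, missing_fraction_night >= 0,
            missing_fraction_night < 1)
  structure(list(sd_base = sd_base, sd_slope = sd_slope,
                 missing_fraction_day = missing_fraction_day,
                 missing_fraction_night = missing_fraction_night,
                 family = match.arg(family)),
            class = "noise_params")
}

ar1 <- function(n, phi, sd, init = 0) {
  x <- numeric(n)
  x[1] <- init
  e <- stats::rnorm(n, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
  x
}

#' Generate a synthetic year of meteorological drivers
#'
#' Builds a plausible half-hourly site-year without fluxes: shortwave as
#' potential radiation times an autocorrelated clear-sky index in
#' [0.1, 1]; air temperature as seasonal + diurnal sinusoids plus AR(1)
#' synoptic noise; soil temperature as an exponentially smoothed, lagged
#' copy of air temperature; VPD from saturation vapour pressure with a
#' relative-humidity model (drier afternoons, wetter rain days, floor 0);
#' soil water content from a single-bucket model driven by Poisson rain
#' events and radiation-scaled evaporative drawdown; lognormal wind speed
#' and a two-mode wind-direction climatology. Deterministic under `seed`.
#'
#' @param latitude,longitude,utc_offset site location (degrees, hours).
#' @param year calendar year.
#' @param seed integer seed.
#' @param rain_prob daily rain probability.
#' @param rain_mean mean event rainfall (mm).
#' @param ta_mean,ta_seasonal_amp,ta_diurnal_amp air-temperature climate
#'   (deg C).
#' @param swc_max,swc_min bucket bounds (% vol).
#' @param swc_init initial soil water (% vol).
#' @param et_scale multiplier on the evaporative drawdown (default 1;
#'   larger = faster dry-down, for arid presets).
#' @param site_id identifier stored in the metadata.
#' @return a [flux_year] with `nee` and `nee_qc` columns of `NA` (fluxes
#'   are attached by [generate_truth()] + [add_noise()]).
#' @export
generate_drivers <- function(latitude = 48, longitude = 8, utc_offset = 1,
                             year = 2015, seed = 1,
                             rain_prob = 0.25, rain_mean = 5,
                             ta_mean = 9, ta_seasonal_amp = 10,
                             ta_diurnal_amp = 4,
                             swc_max = 45, swc_min = 4, swc_init = 30,
                             et_scale = 1, site_id = "SYN-Tmp") {
  set.seed(seed)
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:30", year), tz = "UTC")
  ts <- seq(t0, t1, by = 1800)
  n <- length(ts)
  lt <- as.POSIXlt(ts, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  ndays <- max(doy)
  day_of <- rep(seq_len(ndays), times = tabulate(doy))

  swpot <- potential_radiation(latitude, longitude, utc_offset, ts)

  # rain: Bernoulli rain days, exponential event totals, spread over the
  # afternoon half-hours of the day
  rain_day <- stats::rbinom(ndays, 1, rain_prob) == 1
  rain_amt <- ifelse(rain_day, stats::rexp(ndays, 1 / rain_mean), 0)
  precip <- numeric(n)
  for (dd in which(rain_day)) {
    slots <- which(day_of == dd & hour >= 12 & hour < 18)
    w <- stats::rexp(length(slots))
    precip[slots] <- rain_amt[dd] * w / sum(w)
  }

  # clear-sky index: daily AR(1) around 0.75, pushed down on rain days,
  # plus small half-hourly jitter
  ci_day <- 0.75 + ar1(ndays, 0.6, 0.12)
  ci_day[rain_day] <- pmin(ci_day[rain_day], stats::runif(sum(rain_day),
                                                          0.15, 0.45))
  ci <- pmin(1, pmax(0.1, ci_day[day_of] + ar1(n, 0.9, 0.02)))
  sw_in <- swpot * ci
  sw_in[swpot <= 0] <- 0

  # air temperature: seasonal + diurnal + synoptic AR(1)
  year_len <- ndays
  seasonal <- ta_mean + ta_seasonal_amp *
    sin(2 * pi * (doy - 100) / year_len)  # annual peak near day 190
  diurnal <- -ta_diurnal_amp * cos(2 * pi * (hour - 14) / 24)
  synoptic <- ar1(ndays, 0.8, 1.6)
  ta <- seasonal + diurnal * (0.5 + 0.5 * ci) + synoptic[day_of] +
    ar1(n, 0.9, 0.15)

  # soil temperature: EMA of TA with ~2-day time constant (lagged, damped)
  tsoil <- numeric(n)
  tsoil[1] <- mean(ta[1:48])
  k <- 1 / 96
  for (i in 2:n) tsoil[i] <- tsoil[i - 1] + k * (ta[i] - tsoil[i - 1])

  # VPD from saturation vapour pressure and a humidity model (hPa)
  esat <- 6.1078 * exp(17.27 * ta / (ta + 237.3))
  rh <- 0.78 - 0.18 * pmax(0, -cos(2 * pi * (hour - 15) / 24)) +
    ar1(ndays, 0.7, 0.06)[day_of]
  rh[precip > 0] <- pmax(rh[precip > 0], 0.92)
  rh <- pmin(0.995, pmax(0.25, rh))
  vpd <- pmax(0, esat * (1 - rh))

  # soil water: bucket, 1 mm rain ~ 0.4 % vol; ET scales with radiation
  swc <- numeric(n)
  swc[1] <- swc_init
  for (i in 2:n) {
    et <- et_scale * (0.0024 * (sw_in[i] / 500) + 0.0004) *
      (swc[i - 1] - swc_min) / 10
    swc[i] <- min(swc_max, max(swc_min,
                               swc[i - 1] + 0.4 * precip[i] - et))
  }

  # wind: lognormal speed; direction drifts synoptically around the
  # prevailing sector with a mild diurnal rotation
  ws <- exp(0.6 + ar1(n, 0.95, 0.12))
  wd_synoptic <- 225 + ar1(ndays, 0.75, 25)
  wd <- (wd_synoptic[day_of] + 15 * sin(2 * pi * (hour - 9) / 24) +
           stats::rnorm(n, 0, 20)) %% 360

  data <- data.frame(timestamp = ts, nee = NA_real_, nee_qc = NA_real_,
                     sw_in = sw_in, ta = ta, ts = tsoil, swc = swc,
                     vpd = vpd, ws = ws, wd = wd, precip = precip)
  flux_year(data, list(site_id = site_id, latitude = latitude,
                       longitude = longitude, utc_offset = utc_offset))
}

#' Latent GPP/RECO truth for a driver table
#'
#' Evaluates the noise-free flux surfaces of [truth_params] on the drivers
#' of a [flux_year]:
#' `GPP = phen * lue_max * f_light * f_vpd * f_temp * f_swc *
#'  (1 + diffuse_enhancement * (1 - SW_IN/SW_IN_POT)) *
#'  (1 - afternoon_depression * afternoon) * SW_IN` and
#' `RECO = Rref_base * phen_resp * f_swc_resp * LT(Tblend; E0_true) +
#'  pulse`, `NEE = RECO - GPP`. GPP is exactly 0 wherever `SW_IN = 0` and
#' RECO is strictly positive, so the truth respects every constraint the
#' partitioning network encodes.
#'
#' @param fy a [flux_year] with complete drivers (e.g. from
#'   [generate_drivers()]).
#' @param params a [truth_params].
#' @return list of class `synthetic_truth` with `gpp_true`, `reco_true`,
#'   `nee_true`, the `params`, and `pulse_days` (day-of-year indices of
#'   triggered rewetting pulses).
#' @export
generate_truth <- function(fy, params = truth_params()) {
  d <- fy$data
  p <- params
  n <- nrow(d)
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  swpot <- potential_radiation(fy$meta$latitude, fy$meta$longitude,
                               fy$meta$utc_offset, d$timestamp)

  phen <- p$phen_min + (1 - p$phen_min) *
    exp(-((doy - p$phen_peak_doy) / p$phen_width)^2)
  f_light <- 1 / (1 + d$sw_in / p$light_half_saturation)
  f_vpd <- ifelse(d$vpd > p$vpd0,
                  exp(-p$vpd_sensitivity * (d$vpd - p$vpd0)), 1)
  f_temp <- exp(-((d$ta - p$temp_optimum) / p$temp_width)^2)
  f_swc <- 1 / (1 + exp(-(d$swc - p$swc_stress_threshold) / 2))
  diffuse <- ifelse(swpot > 0, pmin(1, pmax(0, 1 - d$sw_in / swpot)), 0)
  afternoon <- pmax(0, pmin(1, (hour - 12.5) / 5.5))
  gpp <- phen * p$lue_max * f_light * f_vpd * f_temp * f_swc *
    (1 + p$diffuse_enhancement * diffuse) *
    (1 - p$afternoon_depression * afternoon) * d$sw_in
  gpp[d$sw_in <= 0] <- 0

  tblend <- (1 - p$ts_weight) * d$ta + p$ts_weight * d$ts
  f_swc_resp <- 0.25 + 0.75 /
    (1 + exp(-(d$swc - p$swc_resp_threshold) / 2.5))
  phen_resp <- 0.4 + 0.6 * phen
  reco <- p$Rref_base * phen_resp * f_swc_resp *
    lloyd_taylor(tblend, p$E0_true, Rref = 1)

  pulse_days <- integer(0)
  if (p$pulse_amplitude > 0) {
    day_f <- factor(doy, levels = sort(unique(doy)))
    swc_daily <- as.numeric(tapply(d$swc, day_f, mean))
    rain_daily <- as.numeric(tapply(d$precip %||% 0, day_f, sum))
    dry <- swc_daily < p$swc_resp_threshold
    run <- 0L
    for (dd in seq_along(dry)) {
      if (rain_daily[dd] >= 2 && run >= p$pulse_dry_days) {
        pulse_days <- c(pulse_days, dd)
        run <- 0L
      } else if (dry[dd]) run <- run + 1L else run <- 0L
    }
    if (length(pulse_days)) {
      t_day <- doy - 1 + hour / 24
      for (te in pulse_days) {
        dt <- t_day - (te - 1 + 0.5)
        add <- p$pulse_amplitude * exp(-dt / p$pulse_decay_days)
        add[dt < 0] <- 0
        reco <- reco + add
      }
    }
  }
  structure(list(gpp_true = gpp, reco_true = reco,
                 nee_true = reco - gpp, params = p,
                 pulse_days = pulse_days),
            class = "synthetic_truth")
}

rlaplace <- function(n, sd) {
  b <- sd / sqrt(2)
  stats::rexp(n, 1) * b - stats::rexp(n, 1) * b
}

#' Attach noisy NEE observations to a synthetic truth
#'
#' `NEE_obs = NEE_true + noise`, with noise drawn from the configured
#' family at standard deviation `sd_base + sd_slope * |NEE_true|`.
#' A random fraction of day and night records is set to missing
#' (`nee = NA`, `nee_qc = 1`); retained records get `nee_qc = 0`.
#' Deterministic under `seed`.
#'
#' @param fy driver [flux_year] (from [generate_drivers()]).
#' @param truth a [synthetic_truth][generate_truth].
#' @param noise a [noise_params].
#' @param seed integer seed.
#' @param night_threshold_wm2 W m-2 day/night threshold for the missing
#'   fractions (default 20).
#' @return a [flux_year] with observed `nee` and `nee_qc` filled in.
#' @export
add_noise <- function(fy, truth, noise = noise_params(), seed = 1,
                      night_threshold_wm2 = 20) {
  set.seed(seed)
  d <- fy$data
  n <- nrow(d)
  sd_i <- noise$sd_base + noise$sd_slope * abs(truth$nee_true)
  eps <- if (noise$family == "laplace") rlaplace(n, sd_i) else
    stats::rnorm(n, 0, sd_i)
  nee_obs <- truth$nee_true + eps
  night <- is_night(d$sw_in, threshold = night_threshold_wm2)
  drop <- logical(n)
  drop[!night] <- stats::runif(sum(!night)) < noise$missing_fraction_day
  drop[night] <- stats::runif(sum(night)) < noise$missing_fraction_night
  d$nee <- ifelse(drop, NA_real_, nee_obs)
  d$nee_qc <- ifelse(drop, 1, 0)
  flux_year(d, fy$meta)
}

#' Generate a complete synthetic site-year with known truth
#'
#' Convenience wrapper chaining [generate_drivers()], [generate_truth()]
#' and [add_noise()]. Two presets are provided: `"temperate-grass"`
#' (default; annual GPP around 1,500 g C m-2 yr-1, no respiration pulse)
#' and `"semiarid-grass"` (dry site: sparse rain, strong soil-water control
#' and a post-rewetting respiration pulse).
#'
#' @param preset `"temperate-grass"` or `"semiarid-grass"`.
#' @param seed integer master seed for drivers and noise.
#' @param year calendar year (default 2015).
#' @param truth optional [truth_params] override.
#' @param noise optional [noise_params] override.
#' @return list with `table` (a [flux_year] with noisy NEE), `truth`
#'   (a [synthetic_truth][generate_truth]), `noise`, `preset`, `seed`.
#' @export
synth_site_year <- function(preset = c("temperate-grass",
                                       "semiarid-grass"),
                            seed = 1, year = 2015, truth = NULL,
                            noise = noise_params()) {
  preset <- match.arg(preset)
  if (preset == "temperate-grass") {
    drv <- generate_drivers(latitude = 48, longitude = 8, utc_offset = 1,
                            year = year, seed = seed,
                            site_id = "SYN-Tmp")
    tp <- truth %||% truth_params()
  } else {
    drv <- generate_drivers(latitude = 32, longitude = -110,
                            utc_offset = -7, year = year, seed = seed,
                            rain_prob = 0.08, rain_mean = 9,
                            ta_mean = 17, ta_seasonal_amp = 9,
                            ta_diurnal_amp = 7, swc_init = 10,
                            swc_max = 28, swc_min = 3, et_scale = 5,
                            site_id = "SYN-Dry")
    tp <- truth %||% truth_params(lue_max = 0.05,
                                  swc_stress_threshold = 11,
                                  swc_resp_threshold = 10,
                                  temp_optimum = 27,
                                  Rref_base = 1.4,
                                  pulse_amplitude = 3,
                                  pulse_decay_days = 2,
                                  phen_peak_doy = 210,
                                  phen_width = 90, phen_min = 0.15)
  }
  tr <- generate_truth(drv, tp)
  tbl <- add_noise(drv, tr, noise, seed = seed + 1)
  list(table = tbl, truth = tr, noise = noise, preset = preset,
       seed = seed)
}
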