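test_that("driver generation is seed-deterministic and physically bounded", {
  a <- generate_drivers(seed = 3)
  b <- generate_drivers(seed = 3)
  expect_equal(a$data, b$data)
  c_ <- generate_drivers(seed = 4)
  expect_false(identical(a$data$ta, c_$data$ta))

  d <- a$data
  swpot <- potential_radiation(48, 8, 1, d$timestamp)
  expect_true(all(d$sw_in[swpot == 0] == 0))
  expect_true(all(d$swc >= 0 & d$swc <= 100))
  expect_true(all(d$vpd >= 0))
  expect_true(all(d$ws > 0))
  expect_true(all(d$wd >= 0 & d$wd < 360))
  # soil water rises only when it rains
  up <- which(diff(d$swc) > 1e-9) + 1L
  expect_true(all(d$precip[up] > 0))
})

test_that("latent truth obeys the constraints the network encodes", {
  syn <- fixture_syn()
  tr <- syn$truth
  d <- syn$table$data
  expect_equal(tr$nee_true, tr$reco_true - tr$gpp_true)
  expect_true(all(tr$gpp_true[d$sw_in == 0] == 0))
  expect_true(all(tr$reco_true > 0))
  # Lloyd-Taylor reference identity at the blended reference temperature
  p <- truth_params(ts_weight = 0, afternoon_depression = 0,
                    diffuse_enhancement = 0)
  drv <- generate_drivers(seed = 6)
  d2 <- drv$data
  d2$ta <- rep(15, nrow(d2))  # blended T = Tref
  tr2 <- generate_truth(flux_year(d2, drv$meta), p)
  lt <- as.POSIXlt(d2$timestamp, tz = "UTC")
  doy <- lt$yday + 1
  phen <- p$phen_min + (1 - p$phen_min) *
    exp(-((doy - p$phen_peak_doy) / p$phen_width)^2)
  phen_resp <- 0.4 + 0.6 * phen
  f_swc_resp <- 0.25 + 0.75 /
    (1 + exp(-(d2$swc - p$swc_resp_threshold) / 2.5))
  expect_equal(tr2$reco_true, p$Rref_base * phen_resp * f_swc_resp,
               tolerance = 1e-12)
})

test_that("memoryless truth collapses the diel hysteresis loops", {
  drv <- generate_drivers(seed = 6)
  p0 <- truth_params(ts_weight = 0, afternoon_depression = 0,
                     diffuse_enhancement = 0)
  tr0 <- generate_truth(drv, p0)
  tr1 <- generate_truth(drv, truth_params())
  d <- drv$data
  ta_c <- mean_diurnal_cycle(d$ta, d$timestamp, 7:8)
  sw_c <- mean_diurnal_cycle(d$sw_in, d$timestamp, 7:8)
  h0_reco <- hysteresis_area(ta_c, mean_diurnal_cycle(
    log(tr0$reco_true), d$timestamp, 7:8))
  h1_reco <- hysteresis_area(ta_c, mean_diurnal_cycle(
    log(tr1$reco_true), d$timestamp, 7:8))
  expect_lt(abs(h0_reco$normalized), 0.02)
  expect_gt(abs(h1_reco$normalized), abs(h0_reco$normalized))
  h0_gpp <- hysteresis_area(sw_c, mean_diurnal_cycle(
    tr0$gpp_true, d$timestamp, 7:8))
  h1_gpp <- hysteresis_area(sw_c, mean_diurnal_cycle(
    tr1$gpp_true, d$timestamp, 7:8))
  expect_gt(abs(h1_gpp$normalized), abs(h0_gpp$normalized))
})

test_that("respiration pulses appear only when armed and requested", {
  syn_dry <- synth_site_year("semiarid-grass", seed = 1)
  expect_gt(length(syn_dry$truth$pulse_days), 0)
  tp0 <- syn_dry$truth$params
  tp0$pulse_amplitude <- 0
  drv <- generate_drivers(latitude = 32, longitude = -110,
                          utc_offset = -7, seed = 1, rain_prob = 0.08,
                          rain_mean = 9, ta_mean = 17,
                          ta_seasonal_amp = 9, ta_diurnal_amp = 7,
                          swc_init = 10, swc_max = 28, swc_min = 3,
                          et_scale = 5)
  tr0 <- generate_truth(drv, tp0)
  expect_length(tr0$pulse_days, 0)
  # with the pulse on, respiration right after the event exceeds the
  # pulse-free surface by roughly the amplitude
  tr1 <- generate_truth(drv, syn_dry$truth$params)
  doy <- as.POSIXlt(drv$data$timestamp, tz = "UTC")$yday + 1
  ev <- tr1$pulse_days[1]
  sel <- doy == ev + 1
  expect_gt(mean(tr1$reco_true[sel] - tr0$reco_true[sel]), 0.5)
})

test_that("observation noise is unbiased, heteroscedastic and drops the
           stated day/night fractions", {
  syn <- fixture_syn()
  d <- syn$table$data
  resid <- d$nee - syn$truth$nee_true
  n_ok <- sum(is.finite(resid))
  se <- sd(resid, na.rm = TRUE) / sqrt(n_ok)
  expect_lt(abs(mean(resid, na.rm = TRUE)), 3 * se)

  night <- is_night(d$sw_in)
  expect_equal(mean(is.na(d$nee[night])), 0.5, tolerance = 0.05)
  expect_equal(mean(is.na(d$nee[!night])), 0.3, tolerance = 0.05)

  # noise sd grows with |NEE|
  big <- abs(syn$truth$nee_true) > 10
  expect_gt(sd(resid[big], na.rm = TRUE), sd(resid[!big], na.rm = TRUE))

  # near-zero noise and no gaps reproduce the truth
  tiny <- noise_params(sd_base = 1e-9, sd_slope = 0,
                       missing_fraction_day = 0,
                       missing_fraction_night = 0)
  drv <- generate_drivers(seed = 6)
  tr <- generate_truth(drv, truth_params())
  tbl <- add_noise(drv, tr, tiny, seed = 2)
  expect_equal(tbl$data$nee, tr$nee_true, tolerance = 1e-6)
  expect_true(all(tbl$data$nee_qc == 0))
})

test_that("binned truth responses show the expected ecosystem shapes", {
  syn <- fixture_syn()
  d <- syn$table$data
  day <- !is_night(d$sw_in)
  # saturating light response of GPP
  br <- binned_response(syn$truth$gpp_true[day], d$sw_in[day],
                        d$timestamp[day], months = 6:8)
  k <- nrow(br)
  expect_true(all(diff(br$flux_mean[1:5]) > 0))  # steep rise at low light
  slope_lo <- (br$flux_mean[2] - br$flux_mean[1]) /
    (br$driver_mean[2] - br$driver_mean[1])
  slope_hi <- abs(br$flux_mean[k] - br$flux_mean[k - 1]) /
    (br$driver_mean[k] - br$driver_mean[k - 1])
  expect_lt(slope_hi, slope_lo / 5)              # plateau at high light
  # increasing respiration with temperature
  br2 <- binned_response(syn$truth$reco_true, d$ta, d$timestamp,
                         months = 4:9)
  expect_gt(cor(br2$driver_mean, br2$flux_mean), 0.9)
})
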