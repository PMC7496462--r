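test_that("potential radiation matches geometry and an independent oracle", {
  ts_midnight <- as.POSIXct("2015-06-21 00:00", tz = "UTC")
  expect_equal(potential_radiation(45, 0, 0, ts_midnight), 0)

  # equator, equinox, solar noon: cos(zenith) ~ 1
  ts_noon <- as.POSIXct("2015-03-20 11:45", tz = "UTC")  # midpoint ~ noon
  v <- potential_radiation(0, 0, 0, ts_noon)
  expect_equal(v, 1361, tolerance = 0.02)

  # 45 N, DOY 172, solar noon vs independent Cooper/Duffie-Beckman oracle
  ts172 <- as.POSIXct("2015-06-21 11:45", tz = "UTC")
  expect_equal(potential_radiation(45, 0, 0, ts172),
               oracle_potential_radiation(45, 0, 0, ts172),
               tolerance = 0.01)

  # a full day, arbitrary site: nonnegative, zero at night, 2% agreement
  # (the oracle uses the coarser Cooper declination and one-term distance)
  day <- seq(as.POSIXct("2015-09-10", tz = "UTC"), by = 1800,
             length.out = 48)
  imp <- potential_radiation(-20, 30, 2, day)
  ora <- oracle_potential_radiation(-20, 30, 2, day)
  expect_true(all(imp >= 0))
  expect_lt(max(abs(imp - ora)), 0.02 * max(ora))
})

test_that("cyclic encoding identifies the two ends of the domain", {
  e0 <- encode_cyclic(0, 360)
  e360 <- encode_cyclic(360, 360)
  expect_equal(e0$sin, e360$sin)
  expect_equal(e0$cos, e360$cos)
  expect_equal(c(e0$sin, e0$cos), c(0, 1))
  d0 <- encode_cyclic(0, 365)
  d365 <- encode_cyclic(365, 365)
  expect_equal(c(d0$sin, d0$cos), c(d365$sin, d365$cos))
  e90 <- encode_cyclic(90, 360)
  expect_equal(c(e90$sin, e90$cos), c(1, 0), tolerance = 1e-12)
  # exact periodicity property
  v <- runif(20, 0, 360)
  a <- encode_cyclic(v, 360)
  b <- encode_cyclic(v + 360, 360)
  expect_equal(a$sin, b$sin)
  expect_equal(a$cos, b$cos)
})

test_that("nighttime classification uses the 20 W m-2 strict threshold", {
  expect_true(is_night(19.9))
  expect_false(is_night(20.0))
  expect_true(is_night(NA, sw_in_pot = 0))
  expect_false(is_night(NA, sw_in_pot = 50))
})

test_that("daily light aggregates and derivatives", {
  ts2 <- seq(as.POSIXct("2015-01-01", tz = "UTC"), by = 1800,
             length.out = 96)
  const <- rep(5, 96)
  a <- daily_light_aggregates(const, ts2)
  expect_true(all(a$d_halfhourly == 0))
  expect_true(all(a$d_daily == 0))

  two_day <- c(rep(100, 48), rep(110, 48))
  b <- daily_light_aggregates(two_day, ts2)
  expect_equal(unique(b$daily_mean), c(100, 110))
  expect_equal(b$d_daily[1], 10)

  syn <- fixture_syn()
  swpot <- potential_radiation(48, 8, 1, syn$table$data$timestamp)
  y <- daily_light_aggregates(swpot, syn$table$data$timestamp)
  peak_day <- as.POSIXlt(syn$table$data$timestamp[
    which.max(y$daily_mean)])$yday + 1
  expect_gt(peak_day, 150)  # northern site peaks near the solstice
  expect_lt(peak_day, 195)
})

test_that("daily NEE proxies follow the adopted GPP-proxy form", {
  # 2 days, 48 half-hours each, half day half night
  ts2 <- seq(as.POSIXct("2015-07-01", tz = "UTC"), by = 1800,
             length.out = 96)
  night <- rep(rep(c(TRUE, FALSE), each = 24), 2)
  nee <- ifelse(night, 3, -5)
  pr <- daily_nee_proxies(nee, night, ts2)
  expect_equal(unique(pr$k), 0.5)
  expect_equal(unique(pr$nee_night), 3)
  expect_equal(unique(pr$gpp_prox), (3 - (-5)) * 0.5)  # = 4.0
  # no apparent uptake -> proxy 0
  pr0 <- daily_nee_proxies(rep(2, 96), night, ts2)
  expect_equal(unique(pr0$gpp_prox), 0)
  # polar-day fallback: day 2 has no nighttime records
  night2 <- c(night[1:48], rep(FALSE, 48))
  pr2 <- daily_nee_proxies(nee, night2, ts2)
  expect_equal(unique(pr2$nee_night[49:96]), 3)  # carried forward
  expect_true(all(pr2$carried[49:96]))
})

test_that("+/-1 normalization is zero-preserving, bounded and invertible", {
  r <- normalize_pm1(c(-2, 0, 4))
  expect_equal(r$x_norm, c(-0.5, 0, 1))
  expect_equal(r$params$xmax, 4)
  expect_equal(r$params$xmin, -4)

  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(200, sd = 10^runif(1, -3, 3))
    nr <- normalize_pm1(x)
    expect_true(all(abs(nr$x_norm) <= 1))
    expect_equal(normalize_pm1(0, nr$params)$x_norm, 0)
    expect_equal(denormalize_pm1(nr$x_norm, nr$params), x,
                 tolerance = 1e-12)
  }

  z <- normalize_pm1(rep(0, 5))
  expect_true(z$params$degenerate)
  expect_equal(z$params$xmax, 1)
  expect_equal(z$x_norm, rep(0, 5))
})

test_that("driver set matches the driver enumeration and normalization", {
  drv <- fixture_drivers()
  expect_equal(ncol(drv$reco_matrix), 9L)
  expect_equal(ncol(drv$gpp_matrix), 12L)
  expect_true(all(abs(drv$reco_matrix) <= 1, na.rm = TRUE))
  expect_true(all(abs(drv$gpp_matrix) <= 1, na.rm = TRUE))
  expect_true(all(drv$sw_in_raw >= 0))
  expect_length(drv$reductions, 0L)

  # a table without wind direction drops its encodings from both branches
  syn <- fixture_syn()
  d <- syn$table$data
  d$wd <- NA_real_
  drv2 <- build_driver_set(flux_year(d, syn$table$meta))
  expect_equal(ncol(drv2$reco_matrix), 7L)
  expect_equal(ncol(drv2$gpp_matrix), 10L)
  expect_setequal(drv2$reductions, c("cos_wd", "sin_wd"))
  expect_error(build_driver_set(flux_year(d, syn$table$meta),
                                reduced_driver_policy = "error"),
               "entirely missing")
})
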