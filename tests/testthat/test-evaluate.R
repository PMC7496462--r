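test_that("consistency statistics match hand computations", {
  a <- c(0.4, 1.7, 2.2, 3.9)
  s <- consistency_stats(a, a)
  expect_equal(c(s$r2, s$rmse, s$bias), c(1, 0, 0))

  s2 <- consistency_stats(a + 1, a)
  expect_equal(c(s2$r2, s2$rmse, s2$bias), c(1, 1, 1))
  expect_equal(s2$bias_gc_per_year, 12.011e-6 * 365.25 * 86400)

  x <- c(0, 1, 2)
  y <- c(0, 2, 3)
  s3 <- consistency_stats(x, y)
  expect_equal(s3$r2, cor(x, y)^2)
  expect_equal(s3$rmse, sqrt(mean((x - y)^2)))
  expect_equal(s3$bias, mean(x - y))

  expect_true(is.na(consistency_stats(c(1, 1, 1), c(1, 2, 3))$r2))
})

test_that("seasonal cycle and anomalies decompose daily series exactly", {
  const <- rep(4.2, 365)
  dec <- seasonal_cycle_and_anomalies(const)
  expect_true(all(dec$seasonal == 4.2))
  expect_true(all(dec$anomaly == 0))
  expect_true(all(dec$centered == 0))

  set.seed(12)
  daily <- sin(2 * pi * (1:365) / 365) * 3 + rnorm(365, 0, 0.5)
  dec2 <- seasonal_cycle_and_anomalies(daily)
  expect_equal(dec2$seasonal + dec2$anomaly, daily)
  expect_lt(abs(mean(dec2$anomaly)), 1e-10)
  expect_equal(dec2$seasonal[1:5], rep(mean(daily[1:5]), 5))
  expect_equal(seasonal_cycle_and_anomalies(1:5)$seasonal, rep(3, 5))
})

test_that("mean diurnal cycle recovers a slot-determined series", {
  syn <- fixture_syn()
  ts <- syn$table$data$timestamp
  lt <- as.POSIXlt(ts, tz = "UTC")
  slot <- lt$hour * 2 + lt$min %/% 30
  f <- sin(2 * pi * slot / 48)
  cyc <- mean_diurnal_cycle(f, ts, months = 3:5)
  expect_equal(unname(cyc), sin(2 * pi * (0:47) / 48), tolerance = 1e-12)
  expect_equal(unname(cyc - mean_diurnal_cycle(f, ts, 3:5)), rep(0, 48))
  # nighttime slots of the latent GPP are exactly zero
  gpp_cyc <- mean_diurnal_cycle(syn$truth$gpp_true, ts, months = 12)
  expect_equal(unname(gpp_cyc[c(1:10, 45:48)]), rep(0, 14))
})

test_that("hysteresis area implements the shoelace with normalization", {
  # counterclockwise unit square
  x <- c(0, 1, 1, 0)
  y <- c(0, 0, 1, 1)
  h <- hysteresis_area(x, y)
  expect_equal(h$area, 1)
  expect_equal(h$normalized, 1)
  expect_equal(h$orientation, "counterclockwise")
  # out-and-back single-valued trace has zero area
  xv <- c(seq(0, 1, length.out = 10), seq(1, 0, length.out = 10))
  h0 <- hysteresis_area(xv, xv^2)
  expect_equal(h0$area, 0, tolerance = 1e-12)
  # degenerate zero-range cycle is flagged
  hd <- hysteresis_area(rep(1, 5), 1:5)
  expect_true(hd$degenerate)
  expect_equal(hd$area, 0)
  # invariance under affine rescaling after normalization
  set.seed(3)
  xs <- rnorm(48)
  ys <- rnorm(48)
  h1 <- hysteresis_area(xs, ys)
  h2 <- hysteresis_area(10 * xs + 3, 0.2 * ys - 7)
  expect_equal(h2$normalized, h1$normalized, tolerance = 1e-12)
})

test_that("binned responses honour bin count, degenerate drivers and
           linearity", {
  ts <- fixture_syn()$table$data$timestamp[1:2000]
  drvv <- runif(2000, 0, 10)
  br <- binned_response(2 * drvv, drvv, ts, months = 1)
  expect_lte(nrow(br), 10)
  expect_equal(br$flux_mean, 2 * br$driver_mean, tolerance = 1e-10)
  br1 <- binned_response(rnorm(2000), rep(3, 2000), ts, months = 1)
  expect_equal(nrow(br1), 1L)
  expect_equal(br1$driver_mean, 3)
})

test_that("functional-response probes respect the architecture", {
  drv <- fixture_drivers()
  st <- network_structure(3, 4, 9, 12)
  set.seed(81)
  ens <- structure(list(final_members = list(
    list(params = init_network(st)), list(params = init_network(st)))),
    class = "flux_ensemble")
  pr <- functional_response_probe(ens, drv, "sw_in",
                                  grid = seq(0, 800, by = 100))
  expect_equal(pr$mean[pr$grid == 0], 0)   # night-zero survives the probe
  expect_equal(ncol(pr), 3 + 2)            # grid, 2 members, mean, flag
  expect_false(any(pr$extrapolated))
  expect_warning(
    functional_response_probe(ens, drv, "ta", grid = c(0, 200)),
    "normalization range")
  expect_error(
    functional_response_probe(ens, drv, "nee_night", grid = 0:1,
                              branch = "gpp"),
    "not an input")
})

test_that("midday LUE is binned against the diffuse-radiation proxy", {
  syn <- fixture_syn()
  d <- syn$table$data
  res <- list(gpp_pred = syn$truth$gpp_true)
  tab <- lue_vs_diffuse(res, syn$table)
  expect_true(all(tab$proxy_mean >= 0 & tab$proxy_mean <= 1))
  expect_true(all(tab$n >= 5))
  # the generator enhances LUE under diffuse light: increasing trend
  expect_gt(cor(tab$proxy_mean, tab$lue_mean), 0.8)
  tabn <- lue_vs_diffuse(res, syn$table, normalize = TRUE)
  expect_equal(max(tabn$lue_mean), 1)
})
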