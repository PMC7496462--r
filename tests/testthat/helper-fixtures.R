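# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture_syn <- function() {
  if (is.null(.fixtures$syn)) .fixtures$syn <- synth_site_year(seed = 1)
  .fixtures$syn
}

fixture_drivers <- function() {
  if (is.null(.fixtures$drv)) {
    .fixtures$drv <- build_driver_set(fixture_syn()$table)
  }
  .fixtures$drv
}

# A short half-hourly table for io tests (allow_partial).
toy_table <- function(n = 6, start = "2020-01-01 00:00") {
  ts <- seq(as.POSIXct(start, tz = "UTC"), by = 1800, length.out = n)
  data.frame(timestamp = ts,
             nee = seq_len(n) * 0.5, nee_qc = 0,
             sw_in = rep(c(0, 100), length.out = n),
             ta = 10 + seq_len(n), ts = 9 + seq_len(n),
             swc = 20, vpd = 5, ws = 2, wd = 90, precip = 0)
}

toy_meta <- function() {
  list(site_id = "TOY", latitude = 48, longitude = 8, utc_offset = 1)
}

write_toy_csv <- function(path, timestamps = c("202001010000",
                                               "202001010030",
                                               "202001010100"),
                          nee = c(1.5, -9999, 0.2)) {
  df <- data.frame(TIMESTAMP_START = timestamps,
                   NEE_CUT_USTAR50 = nee,
                   NEE_CUT_USTAR50_QC = 0,
                   SW_IN_F = 0, TA_F = 5)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent solar-geometry oracle (Cooper declination, Duffie-Beckman
# forms), deliberately a different formulation from the implementation.
oracle_potential_radiation <- function(latitude, longitude, utc_offset,
                                       timestamp) {
  lt <- as.POSIXlt(timestamp + 900, tz = "UTC")
  n <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + n) / 365)
  B <- 2 * pi * (n - 1) / 365
  E <- 229.2 * (0.000075 + 0.001868 * cos(B) - 0.032077 * sin(B) -
                0.014615 * cos(2 * B) - 0.04089 * sin(2 * B))
  solar_time <- hour + (4 * longitude - 60 * utc_offset + E) / 60
  ha <- (solar_time - 12) * 15 * pi / 180
  lat <- latitude * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  d2 <- 1 + 0.033 * cos(2 * pi * n / 365)
  1361 * d2 * pmax(0, cosz)
}
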