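#' Top-of-atmosphere potential shortwave radiation
#'
#' Computes extraterrestrial shortwave irradiance on a horizontal plane,
#' `S0 * max(0, cos(zenith)) / d^2`, with the solar zenith from standard
#' solar-position equations (Spencer fractional-year series for declination,
#' equation of time and Earth-Sun distance) and the solar constant
#' `S0 = 1361` W m-2. Each half-hour interval is evaluated at its midpoint.
#'
#' @param latitude,longitude site coordinates in degrees (east positive).
#' @param utc_offset local standard time offset from UTC in hours.
#' @param timestamps POSIXct interval-start timestamps (local standard time).
#' @param solar_constant solar constant in W m-2 (default 1361).
#' @return numeric vector of potential radiation (W m-2), zero when the sun
#'   is below the horizon.
#' @export
potential_radiation <- function(latitude, longitude, utc_offset, timestamps,
                                solar_constant = 1361) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90")
  mid <- as.POSIXlt(timestamps + 900, tz = "UTC")  # interval midpoint
  doy <- mid$yday + 1L
  hour <- mid$hour + mid$min / 60 + mid$sec / 3600
  year_len <- ifelse((mid$year + 1900) %% 4 == 0 &
                     ((mid$year + 1900) %% 100 != 0 |
                      (mid$year + 1900) %% 400 == 0), 366, 365)
  g <- 2 * pi / year_len * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  dist2 <- 1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)  # (r0/r)^2
  time_offset <- eqtime + 4 * longitude - 60 * utc_offset
  tst <- hour * 60 + time_offset                   # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180                 # hour angle, rad
  lat <- latitude * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  solar_constant * dist2 * pmax(0, cosz)
}

#' Sine/cosine encoding of a cyclic variable
#'
#' Maps a value in a cyclic domain (wind direction, day of year) to the unit
#' circle so the two ends of the domain coincide:
#' `(sin(2*pi*v/period), cos(2*pi*v/period))`.
#'
#' @param value numeric vector.
#' @param period cycle length in the same units (e.g. 360 for degrees).
#' @return list with components `sin` and `cos`.
#' @export
encode_cyclic <- function(value, period) {
  if (period <= 0) stop("period must be > 0")
  a <- 2 * pi * (value %% period) / period
  list(sin = sin(a), cos = cos(a))
}

#' Classify half-hours as nighttime
#'
#' A record is nighttime when incoming shortwave radiation is below the
#' threshold (default 20 W m-2, strict inequality). Where `sw_in` is
#' missing the classification falls back to `sw_in_pot == 0` (sun below the
#' horizon).
#'
#' @param sw_in measured shortwave (W m-2), may contain `NA`.
#' @param sw_in_pot potential radiation used as fallback (same length), or
#'   `NULL` to leave missing records `NA`.
#' @param threshold W m-2, default 20.
#' @return logical vector.
#' @export
is_night <- function(sw_in, sw_in_pot = NULL, threshold = 20) {
  if (threshold < 0) stop("threshold must be >= 0")
  night <- sw_in < threshold
  if (!is.null(sw_in_pot)) {
    miss <- is.na(night)
    night[miss] <- sw_in_pot[miss] <= 0
  }
  night
}

#' Daily aggregates and first derivatives of potential radiation
#'
#' @param sw_in_pot half-hourly potential radiation (complete series).
#' @param timestamps matching POSIXct timestamps (used for calendar-day
#'   grouping).
#' @return list with `d_halfhourly` (forward difference per half hour, last
#'   value repeated), `daily_mean` (per-day mean broadcast to half hours) and
#'   `d_daily` (forward difference of the daily means, broadcast).
#' @export
daily_light_aggregates <- function(sw_in_pot, timestamps) {
  day <- as.Date(timestamps, tz = "UTC")
  dmean <- tapply(sw_in_pot, day, mean)
  fwd <- function(x) c(diff(x), if (length(x) > 1) diff(x)[length(x) - 1]
                       else 0)
  ddaily <- fwd(as.numeric(dmean))
  idx <- match(day, names(dmean))
  list(d_halfhourly = fwd(sw_in_pot),
       daily_mean = as.numeric(dmean)[idx],
       d_daily = ddaily[idx])
}

#' Mean-diurnal-variation gap filling
#'
#' Fills missing half-hourly values with the mean of available values in the
#' same half-hour-of-day slot within a +/- `window_days` window; remaining
#' gaps fall back to the slot mean over the whole year, then to the overall
#' mean. Used to obtain the continuous NEE series required by the daily
#' NEE-derived drivers.
#'
#' @param x half-hourly series with gaps.
#' @param timestamps POSIXct timestamps.
#' @param window_days half-width of the moving window (default 7).
#' @return gap-free numeric vector.
#' @export
fill_mdv <- function(x, timestamps, window_days = 7) {
  n <- length(x)
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  slot <- lt$hour * 2L + lt$min %/% 30L
  day <- as.integer(as.Date(timestamps, tz = "UTC"))
  filled <- x
  miss <- which(is.na(x))
  if (!length(miss)) return(filled)
  for (i in miss) {
    cand <- which(slot == slot[i] & abs(day - day[i]) <= window_days &
                  !is.na(x))
    if (length(cand)) filled[i] <- mean(x[cand])
  }
  still <- is.na(filled)
  if (any(still)) {
    slot_mean <- tapply(x, slot, mean, na.rm = TRUE)
    filled[still] <- slot_mean[as.character(slot[still])]
  }
  filled[is.na(filled)] <- mean(x, na.rm = TRUE)
  filled
}

#' Daily NEE-derived seasonal drivers
#'
#' Per calendar day: `NEE_NIGHT` = mean nighttime NEE, `NEE_DAY` = mean
#' daytime NEE, `k` = fraction of daytime records, and the GPP proxy
#' `GPP_prox = (NEE_NIGHT - NEE_DAY) * k`, nonnegative whenever nights
#' respire more than days take up (sign convention NEE = RECO - GPP). All
#' are broadcast back to half-hours. Days without nighttime records (polar
#' day) carry `NEE_NIGHT` forward from the most recent valid day and are
#' flagged.
#'
#' @param nee_filled continuous (gap-filled) half-hourly NEE.
#' @param night_flag logical nighttime classification.
#' @param timestamps POSIXct timestamps.
#' @return list with half-hourly `nee_night`, `nee_day`, `gpp_prox`, `k`,
#'   and logical `carried` marking carried-forward days.
#' @export
daily_nee_proxies <- function(nee_filled, night_flag, timestamps) {
  day <- as.integer(as.Date(timestamps, tz = "UTC"))
  ud <- unique(day)
  f <- factor(day, levels = ud)
  n_tot <- tabulate(f)
  n_day <- tapply(!night_flag, f, sum)
  k <- as.numeric(n_day) / n_tot
  mean_by <- function(v, keep) {
    s <- tapply(ifelse(keep, v, NA_real_), f, mean, na.rm = TRUE)
    as.numeric(s)
  }
  nee_night <- mean_by(nee_filled, night_flag)
  nee_day <- mean_by(nee_filled, !night_flag)
  carried <- !is.finite(nee_night)
  if (any(carried)) {
    last <- NA_real_
    for (i in seq_along(nee_night)) {
      if (is.finite(nee_night[i])) last <- nee_night[i]
      else if (is.finite(last)) nee_night[i] <- last
    }
    # leading all-day period: carry backwards from the first valid day
    first_ok <- which(is.finite(nee_night))[1]
    if (is.na(first_ok)) stop("no nighttime records in the whole year")
    nee_night[seq_len(first_ok - 1)] <- nee_night[first_ok]
  }
  nee_day[!is.finite(nee_day)] <- nee_night[!is.finite(nee_day)]
  gpp_prox <- (nee_night - nee_day) * k
  idx <- match(day, ud)
  list(nee_night = nee_night[idx], nee_day = nee_day[idx],
       gpp_prox = gpp_prox[idx], k = k[idx], carried = carried[idx])
}

#' Zero-preserving +/-1 normalization
#'
#' `Xnorm = 2 * ((X - Xmin)/(Xmax - Xmin) - 0.5)` with `Xmax = max|X|` and
#' `Xmin = -Xmax`, which reduces to `X / max|X|`: a linear, invertible map
#' onto `[-1, 1]` that keeps zero at zero. An all-zero (or all-missing)
#' series gets the sentinel `xmax = 1` and is flagged, keeping the transform
#' defined.
#'
#' @param x numeric series (`NA` allowed; at least one finite value needed
#'   for a meaningful scale).
#' @param params optionally reuse previously computed parameters.
#' @return list with `x_norm` and `params` (fields `xmin`, `xmax`,
#'   `degenerate`).
#' @export
normalize_pm1 <- function(x, params = NULL) {
  if (is.null(params)) {
    xmax <- suppressWarnings(max(abs(x), na.rm = TRUE))
    degenerate <- !is.finite(xmax) || xmax == 0
    if (degenerate) xmax <- 1
    params <- list(xmin = -xmax, xmax = xmax, degenerate = degenerate)
  }
  x_norm <- 2 * ((x - params$xmin) / (params$xmax - params$xmin) - 0.5)
  list(x_norm = x_norm, params = params)
}

#' Invert [normalize_pm1()]
#' @param x_norm normalized values.
#' @param params parameters from [normalize_pm1()].
#' @return values on the original scale.
#' @export
denormalize_pm1 <- function(x_norm, params) {
  (x_norm / 2 + 0.5) * (params$xmax - params$xmin) + params$xmin
}

# Driver column enumerations (order is part of the contract).
reco_driver_names <- function() {
  c("ta", "ts", "swc", "ws", "cos_wd", "sin_wd", "sin_doy", "cos_doy",
    "nee_night")
}
gpp_driver_names <- function() {
  c("sw_in", "sw_in_pot", "d_sw_in_pot", "sw_in_pot_daily",
    "d_sw_in_pot_daily", "vpd", "ta", "swc", "ws", "cos_wd", "sin_wd",
    "gpp_prox")
}

#' Assemble the normalized driver matrices for both subnetworks
#'
#' Builds the respiration-branch matrix (air and soil temperature, soil
#' water content, wind speed/direction encodings, day-of-year encodings,
#' daily nighttime NEE) and the GPP-branch matrix (measured and potential
#' shortwave with half-hourly and daily derivatives, VPD, air temperature,
#' soil water, wind, and the daily GPP proxy), each column independently
#' normalized to `[-1, 1]`. The raw shortwave vector is kept unnormalized
#' for the light-use-efficiency product node (scaled by its annual maximum
#' inside the network). Driver variables entirely absent from the table are
#' dropped from the matrices and the reduction recorded (`reductions`),
#' unless `reduced_driver_policy = "error"`.
#'
#' @param fy a [flux_year].
#' @param night_threshold_wm2 W m-2 threshold for the nighttime flag used in
#'   the daily NEE aggregation (default 20).
#' @param solar_constant_wm2 solar constant for the potential radiation.
#' @param reduced_driver_policy `"drop"` (default) or `"error"`.
#' @return An object of class `driver_set`: matrices `reco_matrix` and
#'   `gpp_matrix`, `sw_in_raw`, `night_flag`, `valid_mask` (all required
#'   drivers present), normalization parameters per column (`norm`) and for
#'   the NEE target (`norm_nee`), the normalized measured NEE target
#'   (`nee_norm`, `NA` where not measured), `train_mask`, `timestamps`, and
#'   `reductions`.
#' @export
build_driver_set <- function(fy, night_threshold_wm2 = 20,
                             solar_constant_wm2 = 1361,
                             reduced_driver_policy = c("drop", "error")) {
  reduced_driver_policy <- match.arg(reduced_driver_policy)
  d <- fy$data
  m <- fy$meta
  n <- nrow(d)
  swpot <- potential_radiation(m$latitude, m$longitude, m$utc_offset,
                               d$timestamp,
                               solar_constant = solar_constant_wm2)
  night <- is_night(d$sw_in, sw_in_pot = swpot,
                    threshold = night_threshold_wm2)
  agg <- daily_light_aggregates(swpot, d$timestamp)
  nee_filled <- fill_mdv(d$nee, d$timestamp)
  prox <- daily_nee_proxies(nee_filled, night, d$timestamp)
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  year_len <- ifelse(n == 17568L, 366, 365)
  doy_enc <- encode_cyclic(lt$yday + 1, year_len)
  wd_enc <- if (!is.null(d$wd)) encode_cyclic(d$wd, 360) else
    list(sin = rep(NA_real_, n), cos = rep(NA_real_, n))

  raw <- list(
    ta = d$ta, ts = d$ts, swc = d$swc, ws = d$ws,
    cos_wd = wd_enc$cos, sin_wd = wd_enc$sin,
    sin_doy = doy_enc$sin, cos_doy = doy_enc$cos,
    nee_night = prox$nee_night,
    sw_in = d$sw_in, sw_in_pot = swpot,
    d_sw_in_pot = agg$d_halfhourly, sw_in_pot_daily = agg$daily_mean,
    d_sw_in_pot_daily = agg$d_daily, vpd = d$vpd, gpp_prox = prox$gpp_prox)

  all_missing <- vapply(raw, function(v) all(is.na(v)), logical(1))
  reductions <- character(0)
  keep_col <- function(nm) {
    if (!all_missing[[nm]]) return(TRUE)
    if (reduced_driver_policy == "error") {
      stop("driver entirely missing: ", nm)
    }
    FALSE
  }
  reco_cols <- Filter(keep_col, reco_driver_names())
  gpp_cols <- Filter(keep_col, gpp_driver_names())
  reductions <- setdiff(c(reco_driver_names(), gpp_driver_names()),
                        c(reco_cols, gpp_cols))
  reductions <- unique(reductions[all_missing[reductions]])

  norm <- list()
  normed <- list()
  for (nm in unique(c(reco_cols, gpp_cols))) {
    nr <- normalize_pm1(raw[[nm]])
    norm[[nm]] <- nr$params
    normed[[nm]] <- nr$x_norm
  }
  reco_matrix <- do.call(cbind, normed[reco_cols])
  gpp_matrix <- do.call(cbind, normed[gpp_cols])
  colnames(reco_matrix) <- reco_cols
  colnames(gpp_matrix) <- gpp_cols

  valid_mask <- rowSums(is.na(reco_matrix)) == 0 &
    rowSums(is.na(gpp_matrix)) == 0 & !is.na(d$sw_in)

  nee_measured <- ifelse(!is.na(d$nee_qc) & d$nee_qc == 0, d$nee, NA_real_)
  nn <- normalize_pm1(nee_measured)
  structure(list(
    reco_matrix = reco_matrix, gpp_matrix = gpp_matrix,
    sw_in_raw = d$sw_in, sw_max = max(d$sw_in, na.rm = TRUE),
    night_flag = night, valid_mask = valid_mask,
    norm = norm, norm_nee = nn$params, nee_norm = nn$x_norm,
    train_mask = valid_mask & !is.na(nee_measured),
    timestamps = d$timestamp, reductions = reductions),
    class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf("<driver_set> %d records; RECO drivers: %d, GPP drivers: %d\n",
              length(x$timestamps), ncol(x$reco_matrix),
              ncol(x$gpp_matrix)))
  cat(sprintf("  trainable records: %d\n", sum(x$train_mask)))
  if (length(x$reductions)) {
    cat("  reduced drivers:", paste(x$reductions, collapse = ", "), "\n")
  }
  invisible(x)
}
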