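#' Cross-consistency statistics between two flux series
#'
#' R-squared (squared Pearson correlation), RMSE and bias (`mean(a - b)`),
#' plus the bias expressed as an annual carbon total
#' (g C m-2 yr-1; umol CO2 m-2 s-1 x 12.011 ug C per umol x seconds per
#' year). Pairs with missing values are dropped.
#'
#' @param a,b aligned flux series (umol CO2 m-2 s-1).
#' @return list with `r2` (NA when either series is constant), `rmse`,
#'   `bias`, `bias_gc_per_year`, `n`.
#' @export
consistency_stats <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  x <- a[ok]
  y <- b[ok]
  if (length(x) < 2) stop("need at least 2 finite pairs")
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)^2
  bias <- mean(x - y)
  list(r2 = r2, rmse = sqrt(mean((x - y)^2)), bias = bias,
       bias_gc_per_year = bias * 12.011e-6 * 365.25 * 86400,
       n = length(x))
}

#' Seasonal cycle and daily anomalies of a daily series
#'
#' The seasonal cycle is the mean over non-overlapping 5-day calendar
#' blocks (the final short block averages its remaining days), broadcast
#' back to days; anomalies are daily value minus seasonal cycle; the
#' centred cycle subtracts the annual mean daily value. Missing days are
#' excluded from block means.
#'
#' @param daily numeric vector, one value per calendar day.
#' @param block_days block length (default 5).
#' @return list with `seasonal`, `anomaly`, `centered` (same length as
#'   input).
#' @export
seasonal_cycle_and_anomalies <- function(daily, block_days = 5) {
  n <- length(daily)
  block <- (seq_len(n) - 1L) %/% block_days
  bm <- tapply(daily, block, mean, na.rm = TRUE)
  seasonal <- as.numeric(bm)[block + 1L]
  seasonal[is.nan(seasonal)] <- NA_real_
  list(seasonal = seasonal, anomaly = daily - seasonal,
       centered = seasonal - mean(daily, na.rm = TRUE))
}

#' Mean diurnal cycle over selected months
#'
#' Per half-hour-of-day mean of a half-hourly series restricted to a month
#' subset; slots with no finite value are `NA`. Difference cycles between
#' two methods are obtained by differencing two outputs.
#'
#' @param x half-hourly series.
#' @param timestamps POSIXct timestamps.
#' @param months integer month subset (default all 12).
#' @return numeric vector of length 48 named by starting hour.
#' @export
mean_diurnal_cycle <- function(x, timestamps, months = 1:12) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  keep <- (lt$mon + 1L) %in% months
  slot <- (lt$hour * 2L + lt$min %/% 30L)[keep]
  out <- rep(NA_real_, 48)
  m <- tapply(x[keep], factor(slot, levels = 0:47), mean, na.rm = TRUE)
  out <- as.numeric(m)
  out[is.nan(out)] <- NA_real_
  names(out) <- sprintf("%02d:%02d", (0:47) %/% 2, ((0:47) %% 2) * 30)
  out
}

#' Diel hysteresis area of a flux-driver loop
#'
#' Signed area of the closed polygon traced by `(x(t), y(t))` over the
#' 48-slot mean diurnal cycle, computed with the shoelace formula;
#' positive = counterclockwise. The normalized area divides by
#' `range(x) * range(y)`, making the measure invariant under affine
#' rescaling of either axis. A single-valued response (out-and-back trace)
#' has area 0. Degenerate (zero-range) cycles return area 0 with a flag.
#'
#' @param x_cycle,y_cycle 48-slot driver and flux cycles (NA slots are
#'   dropped pairwise).
#' @return list with `area` (signed, data units), `normalized` (signed),
#'   `orientation` (`"counterclockwise"`, `"clockwise"` or `"none"`),
#'   `degenerate`.
#' @export
hysteresis_area <- function(x_cycle, y_cycle) {
  ok <- is.finite(x_cycle) & is.finite(y_cycle)
  x <- x_cycle[ok]
  y <- y_cycle[ok]
  if (length(x) < 3) return(list(area = 0, normalized = 0,
                                 orientation = "none", degenerate = TRUE))
  xn <- c(x, x[1])
  yn <- c(y, y[1])
  area <- 0.5 * sum(xn[-length(xn)] * yn[-1] - xn[-1] * yn[-length(yn)])
  rx <- diff(range(x))
  ry <- diff(range(y))
  if (rx == 0 || ry == 0) {
    return(list(area = 0, normalized = 0, orientation = "none",
                degenerate = TRUE))
  }
  norm <- area / (rx * ry)
  list(area = area, normalized = norm,
       orientation = if (area > 0) "counterclockwise" else if (area < 0)
         "clockwise" else "none",
       degenerate = FALSE)
}

#' Functional-response probe of a trained ensemble
#'
#' Reproduces the univariate response analysis: all drivers of the probed
#' branch are frozen at their seasonal midday means (records at
#' 11:00-13:00 local standard time within the selected months), the chosen
#' driver is swept over a grid (normalized with the same parameters as in
#' training), and the branch output is evaluated per final member. For GPP
#' probes the shortwave entering the product node follows the sweep when
#' `vary = "sw_in"`, otherwise it is held at the midday mean.
#'
#' @param ensemble a [flux_ensemble][run_ensemble].
#' @param drivers the [driver_set][build_driver_set] used in training.
#' @param vary driver column name (of the probed branch).
#' @param grid physical-unit grid for the varied driver.
#' @param months season as integer months (default 6:8).
#' @param branch `"gpp"` or `"reco"` (default chosen from the driver's
#'   branch membership, preferring GPP).
#' @return data.frame with the grid, per-member responses
#'   (`member_1`, ...), the ensemble `mean`, and an `extrapolated` flag for
#'   grid points outside the normalization range.
#' @export
functional_response_probe <- function(ensemble, drivers, vary, grid,
                                      months = 6:8, branch = NULL) {
  in_gpp <- vary %in% colnames(drivers$gpp_matrix)
  in_reco <- vary %in% colnames(drivers$reco_matrix)
  if (is.null(branch)) branch <- if (in_gpp) "gpp" else "reco"
  if ((branch == "gpp" && !in_gpp) || (branch == "reco" && !in_reco)) {
    stop("driver '", vary, "' is not an input of the ", branch, " branch")
  }
  lt <- as.POSIXlt(drivers$timestamps, tz = "UTC")
  hour <- lt$hour + lt$min / 60
  midday <- (lt$mon + 1L) %in% months & hour >= 11 & hour < 13 &
    drivers$valid_mask
  if (!any(midday)) stop("no valid midday records in the season")
  base_row <- function(M) colMeans(M[midday, , drop = FALSE])
  ng <- length(grid)
  Xg <- matrix(rep(base_row(drivers$gpp_matrix), each = ng), nrow = ng)
  colnames(Xg) <- colnames(drivers$gpp_matrix)
  Xr <- matrix(rep(base_row(drivers$reco_matrix), each = ng), nrow = ng)
  colnames(Xr) <- colnames(drivers$reco_matrix)
  sw_mid <- mean(drivers$sw_in_raw[midday])
  sw_vec <- rep(sw_mid, ng)
  np <- drivers$norm[[vary]]
  grid_norm <- normalize_pm1(grid, np)$x_norm
  if (branch == "gpp") Xg[, vary] <- grid_norm else Xr[, vary] <- grid_norm
  if (vary == "sw_in") sw_vec <- grid
  probe_drivers <- drivers
  probe_drivers$gpp_matrix <- Xg
  probe_drivers$reco_matrix <- Xr
  probe_drivers$sw_in_raw <- sw_vec
  responses <- sapply(ensemble$final_members, function(m) {
    f <- nn_forward(m$params, probe_drivers)
    if (branch == "gpp") f$gpp_pred else f$reco_pred
  })
  responses <- matrix(responses, nrow = ng)
  colnames(responses) <- sprintf("member_%d",
                                 seq_along(ensemble$final_members))
  out <- data.frame(grid = grid, responses, mean = rowMeans(responses),
                    extrapolated = abs(grid_norm) > 1)
  if (any(out$extrapolated)) {
    warning("grid extends beyond the normalization range")
  }
  out
}

#' Binned flux-driver response
#'
#' Splits the driver range within a month window into `n_bins` equal-width
#' intervals and reports the mean driver and mean flux per bin; bins with
#' fewer than `min_points` records are dropped.
#'
#' @param flux,driver aligned half-hourly series.
#' @param timestamps POSIXct timestamps.
#' @param months month subset (default all).
#' @param n_bins number of intervals (default 10).
#' @param min_points minimum records per kept bin (default 5).
#' @return data.frame with `driver_mean`, `flux_mean`, `n` per kept bin.
#' @export
binned_response <- function(flux, driver, timestamps, months = 1:12,
                            n_bins = 10, min_points = 5) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  keep <- (lt$mon + 1L) %in% months & is.finite(flux) & is.finite(driver)
  if (!any(keep)) stop("no finite records in the window")
  f <- flux[keep]
  d <- driver[keep]
  if (diff(range(d)) == 0) {
    return(data.frame(driver_mean = mean(d), flux_mean = mean(f),
                      n = length(d)))
  }
  brk <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- cut(d, brk, include.lowest = TRUE)
  out <- data.frame(
    driver_mean = as.numeric(tapply(d, bin, mean)),
    flux_mean = as.numeric(tapply(f, bin, mean)),
    n = as.numeric(table(bin)))
  out <- out[!is.na(out$driver_mean) & out$n >= min_points, ]
  rownames(out) <- NULL
  out
}

#' Midday light-use efficiency by diffuse-radiation class
#'
#' The diffuse-to-direct radiation ratio is proxied by
#' `1 - SW_IN/SW_IN_POT`, clipped to [0, 1]. Midday records (11:00-13:00,
#' `SW_IN_POT > 0`, `SW_IN > 0`) contribute `LUE = GPP_pred / SW_IN`;
#' means are reported per equal-width proxy bin, optionally max-normalized
#' for cross-site comparison.
#'
#' @param result a `partition_result` (ensemble or baseline).
#' @param fy the matching [flux_year].
#' @param n_bins proxy bins (default 10).
#' @param normalize divide LUE means by their maximum (default `FALSE`).
#' @return data.frame with `proxy_mean`, `lue_mean`, `n` per kept bin.
#' @export
lue_vs_diffuse <- function(result, fy, n_bins = 10, normalize = FALSE) {
  d <- fy$data
  swpot <- potential_radiation(fy$meta$latitude, fy$meta$longitude,
                               fy$meta$utc_offset, d$timestamp)
  lt <- as.POSIXlt(d$timestamp, tz = "UTC")
  hour <- lt$hour + lt$min / 60
  keep <- hour >= 11 & hour < 13 & swpot > 0 & is.finite(d$sw_in) &
    d$sw_in > 0 & is.finite(result$gpp_pred)
  proxy <- pmin(1, pmax(0, 1 - d$sw_in[keep] / swpot[keep]))
  lue <- result$gpp_pred[keep] / d$sw_in[keep]
  brk <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(proxy, brk, include.lowest = TRUE)
  out <- data.frame(proxy_mean = as.numeric(tapply(proxy, bin, mean)),
                    lue_mean = as.numeric(tapply(lue, bin, mean)),
                    n = as.numeric(table(bin)))
  out <- out[!is.na(out$proxy_mean) & out$n >= 5, ]
  if (normalize && nrow(out)) out$lue_mean <- out$lue_mean /
      max(out$lue_mean)
  rownames(out) <- NULL
  out
}

#' Aggregate a half-hourly series to daily means
#'
#' @param x half-hourly series.
#' @param timestamps POSIXct timestamps.
#' @param min_coverage minimum fraction of finite half-hours for a day to
#'   be reported (default 1, i.e. complete days only).
#' @return named numeric vector, one entry per calendar day.
#' @export
daily_means <- function(x, timestamps, min_coverage = 1) {
  day <- as.Date(timestamps, tz = "UTC")
  f <- factor(day)
  m <- tapply(x, f, function(v) {
    if (mean(is.finite(v)) < min_coverage) NA_real_ else
      mean(v, na.rm = TRUE)
  })
  out <- as.numeric(m)
  names(out) <- levels(f)
  out
}
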