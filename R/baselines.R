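#' Lloyd-Taylor respiration model
#'
#' Arrhenius-type temperature response
#' `R(T) = Rref * exp(E0 * (1/(Tref - T0) - 1/(T - T0)))` with the
#' conventional reference temperature `Tref = 15` deg C and
#' `T0 = -46.02` deg C. `E0` is the activation-energy-like temperature
#' sensitivity (K), `Rref` the respiration at `Tref`.
#'
#' @param temp temperature series (deg C); must exceed `T0` everywhere.
#' @param E0 temperature sensitivity (K), > 0 for an increasing response.
#' @param Rref respiration at the reference temperature
#'   (umol CO2 m-2 s-1), > 0.
#' @param Tref,T0 reference constants (deg C).
#' @return respiration series (umol CO2 m-2 s-1).
#' @export
lloyd_taylor <- function(temp, E0, Rref, Tref = 15, T0 = -46.02) {
  if (any(temp <= T0, na.rm = TRUE)) stop("temperature at or below T0")
  Rref * exp(E0 * (1 / (Tref - T0) - 1 / (temp - T0)))
}

# Fit (E0, Rref) to nighttime NEE ~ TA in one window; returns estimates and
# standard errors, or NULL when the fit fails or is ill-determined.
fit_lt_window <- function(ta, nee) {
  ok <- is.finite(ta) & is.finite(nee)
  if (sum(ok) < 2) return(NULL)
  ta <- ta[ok]
  nee <- nee[ok]
  start <- list(E0 = 150, Rref = max(mean(nee), 0.1))
  fit <- tryCatch(
    minpack.lm::nlsLM(nee ~ lloyd_taylor(ta, E0, Rref),
                      start = start,
                      lower = c(E0 = 10, Rref = 1e-3),
                      upper = c(E0 = 600, Rref = 100),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(E0 = NA, Rref = NA))
  list(E0 = co[["E0"]], Rref = co[["Rref"]],
       E0_se = se[["E0"]], Rref_se = se[["Rref"]], n = sum(ok))
}

# Rref at window centres -> half-hourly series by linear interpolation,
# constant extrapolation at the ends.
interp_window_param <- function(centers, values, at) {
  ok <- is.finite(values)
  if (sum(ok) == 0) stop("no valid window parameters to interpolate")
  if (sum(ok) == 1) return(rep(values[ok], length(at)))
  stats::approx(centers[ok], values[ok], xout = at, rule = 2)$y
}

#' Nighttime-method partitioning (simplified)
#'
#' The nighttime reference partitioner: nighttime measured NEE is taken as
#' respiration and fitted to the Lloyd-Taylor curve against air
#' temperature. The temperature sensitivity `E0` is estimated annually by
#' fitting 15-day windows (kept when they hold at least `min_window_points`
#' nighttime records and yield finite parameter standard errors) and
#' averaging the three window estimates with the smallest `E0` standard
#' error. With `E0` fixed, `Rref` is re-fitted in 4-day moving windows
#' (stepped 2 days) by linear regression of nighttime NEE on the fixed
#' temperature shape, and interpolated linearly between window centres.
#' RECO is the Lloyd-Taylor extrapolation at every record; GPP = RECO - NEE
#' at records with observed NEE, forced to 0 at night.
#'
#' @param fy a [flux_year].
#' @param night_threshold_wm2 W m-2 nighttime threshold (default 20).
#' @param min_window_points minimum nighttime records per 15-day E0 window
#'   (default 30).
#' @return list with `result` (class `partition_result`: `timestamp`,
#'   `reco_pred`, `gpp_pred`, `nee_pred`), `E0` (annual value), `E0_windows`
#'   (per-window fits), `rref_windows`, and `fallback` (TRUE when fewer
#'   than 3 usable E0 windows forced a single annual fit).
#' @export
partition_nighttime <- function(fy, night_threshold_wm2 = 20,
                                min_window_points = 30) {
  d <- fy$data
  swpot <- potential_radiation(fy$meta$latitude, fy$meta$longitude,
                               fy$meta$utc_offset, d$timestamp)
  night <- is_night(d$sw_in, sw_in_pot = swpot,
                    threshold = night_threshold_wm2)
  measured <- !is.na(d$nee) & !is.na(d$nee_qc) & d$nee_qc == 0
  fit_mask <- night & measured & is.finite(d$ta)
  day_index <- as.integer(as.Date(d$timestamp, tz = "UTC"))
  day_index <- day_index - min(day_index)          # 0-based day of year

  # --- annual E0 from 15-day windows ------------------------------------
  win_id <- day_index %/% 15L
  wins <- sort(unique(win_id))
  fits <- lapply(wins, function(w) {
    sel <- fit_mask & win_id == w
    if (sum(sel) < min_window_points) return(NULL)
    f <- fit_lt_window(d$ta[sel], d$nee[sel])
    if (is.null(f) || !is.finite(f$E0_se)) return(NULL)
    f$window <- w
    f
  })
  fits <- Filter(Negate(is.null), fits)
  fallback <- length(fits) < 3
  if (!fallback) {
    se <- vapply(fits, `[[`, 0, "E0_se")
    E0 <- mean(vapply(fits[order(se)[1:3]], `[[`, 0, "E0"))
  } else {
    f <- fit_lt_window(d$ta[fit_mask], d$nee[fit_mask])
    if (is.null(f)) stop("annual Lloyd-Taylor fit failed")
    E0 <- f$E0
  }

  # --- Rref in 4-day moving windows with E0 fixed -----------------------
  shape <- lloyd_taylor(d$ta, E0, Rref = 1)         # Rref-free shape
  starts <- seq(0L, max(day_index), by = 2L)
  centers <- starts + 2
  rref <- vapply(starts, function(s) {
    sel <- fit_mask & day_index >= s & day_index < s + 4L
    if (sum(sel) < 6) return(NA_real_)
    # linear in Rref: least squares through the origin on the fixed shape
    max(sum(d$nee[sel] * shape[sel]) / sum(shape[sel]^2), 1e-3)
  }, numeric(1))
  rref_hh <- interp_window_param(centers, rref,
                                 day_index + as.numeric(
                                   format(d$timestamp, "%H")) / 24)
  reco <- lloyd_taylor(d$ta, E0, Rref = 1) * rref_hh
  gpp <- ifelse(measured, reco - d$nee, NA_real_)
  gpp[night] <- 0
  result <- structure(list(timestamp = d$timestamp, reco_pred = reco,
                           gpp_pred = gpp, nee_pred = reco - gpp),
                      class = "partition_result")
  list(result = result, E0 = E0, E0_windows = fits,
       rref_windows = data.frame(center_day = centers, rref = rref),
       fallback = fallback)
}

# DT model NEE prediction given parameters; beta downregulated above vpd0.
dt_nee_model <- function(sw_in, vpd, lt_shape, alpha, beta0, k_vpd,
                         rref, vpd0 = 10) {
  beta <- ifelse(vpd > vpd0, beta0 * exp(-k_vpd * (vpd - vpd0)), beta0)
  gpp <- (alpha * beta * sw_in) / (alpha * sw_in + beta)
  gpp[!is.finite(gpp)] <- 0
  -gpp + rref * lt_shape
}

#' Daytime-method partitioning (simplified)
#'
#' The daytime reference partitioner: a rectangular-hyperbola light
#' response, with maximum uptake downregulated by VPD above `vpd0`
#' (10 hPa), plus Lloyd-Taylor respiration:
#' `NEE = -(alpha*beta*SW_IN)/(alpha*SW_IN + beta) + Rref * LT(TA; E0)`,
#' `beta = beta0 * exp(-k_vpd * (VPD - vpd0))` for `VPD > vpd0`, else
#' `beta0`. `E0` is taken annually from the nighttime records (as in
#' [partition_nighttime()]); `alpha`, `beta0`, `k_vpd` and `Rref` are
#' fitted to daytime measured NEE in 4-day windows stepped 2 days.
#' Non-convergent windows carry the parameters of the nearest converged
#' window. GPP and RECO are reported from the fitted components at every
#' record.
#'
#' @param fy a [flux_year].
#' @param night_threshold_wm2 W m-2 nighttime threshold (default 20).
#' @param vpd0 VPD threshold in hPa above which uptake is downregulated
#'   (default 10).
#' @return list with `result` (class `partition_result`), `E0`, and
#'   `windows` (per-window parameter table with a `converged` flag).
#' @export
partition_daytime <- function(fy, night_threshold_wm2 = 20, vpd0 = 10) {
  d <- fy$data
  swpot <- potential_radiation(fy$meta$latitude, fy$meta$longitude,
                               fy$meta$utc_offset, d$timestamp)
  night <- is_night(d$sw_in, sw_in_pot = swpot,
                    threshold = night_threshold_wm2)
  measured <- !is.na(d$nee) & !is.na(d$nee_qc) & d$nee_qc == 0
  nt <- partition_nighttime(fy, night_threshold_wm2)
  E0 <- nt$E0
  lt_shape <- lloyd_taylor(d$ta, E0, Rref = 1)
  day_index <- as.integer(as.Date(d$timestamp, tz = "UTC"))
  day_index <- day_index - min(day_index)
  fit_mask <- !night & measured & is.finite(d$ta) & is.finite(d$sw_in) &
    is.finite(d$vpd)

  starts <- seq(0L, max(day_index), by = 2L)
  centers <- starts + 2
  par_names <- c("alpha", "beta0", "k_vpd", "rref")
  pars <- matrix(NA_real_, length(starts), 4,
                 dimnames = list(NULL, par_names))
  for (i in seq_along(starts)) {
    sel <- fit_mask & day_index >= starts[i] & day_index < starts[i] + 4L
    if (sum(sel) < 12) next
    df <- data.frame(nee = d$nee[sel], sw = d$sw_in[sel],
                     vpd = d$vpd[sel], shape = lt_shape[sel])
    # stage 1: no VPD downregulation (k_vpd = 0); robust in windows with a
    # weak light response, where the 4-parameter fit is singular
    f1 <- tryCatch(
      minpack.lm::nlsLM(
        nee ~ dt_nee_model(sw, vpd, shape, alpha, beta0, 0, rref,
                           vpd0 = vpd0),
        data = df,
        start = list(alpha = 0.03, beta0 = max(-min(df$nee), 1),
                     rref = max(mean(df$shape), 0.5)),
        lower = c(alpha = 1e-5, beta0 = 1e-3, rref = 1e-3),
        upper = c(alpha = 5, beta0 = 200, rref = 100),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(f1)) next
    co <- stats::coef(f1)
    pars[i, ] <- c(co[["alpha"]], co[["beta0"]], 0, co[["rref"]])
    # stage 2: free k_vpd only when the window samples VPD above vpd0
    if (mean(df$vpd > vpd0) >= 0.1) {
      f2 <- tryCatch(
        minpack.lm::nlsLM(
          nee ~ dt_nee_model(sw, vpd, shape, alpha, beta0, k_vpd, rref,
                             vpd0 = vpd0),
          data = df,
          start = list(alpha = co[["alpha"]], beta0 = co[["beta0"]],
                       k_vpd = 0.05, rref = co[["rref"]]),
          lower = c(alpha = 1e-5, beta0 = 1e-3, k_vpd = 0, rref = 1e-3),
          upper = c(alpha = 5, beta0 = 200, k_vpd = 2, rref = 100),
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(f2) &&
          sum(stats::resid(f2)^2) <= sum(stats::resid(f1)^2)) {
        pars[i, ] <- stats::coef(f2)[par_names]
      }
    }
  }
  converged <- is.finite(pars[, "alpha"])
  if (!any(converged)) stop("no daytime window converged")
  # carry parameters from the nearest converged window
  for (i in which(!converged)) {
    j <- which(converged)[which.min(abs(centers[converged] - centers[i]))]
    pars[i, ] <- pars[j, ]
  }
  # per-window parameter vectors are kept as coherent tuples: the light
  # response is near-degenerate in (alpha, beta0), so blending adjacent
  # windows can produce curves neither window fitted
  hh_day <- day_index + as.numeric(format(d$timestamp, "%H")) / 24
  nearest <- vapply(hh_day, function(t) which.min(abs(centers - t)),
                    integer(1))
  alpha <- pars[nearest, "alpha"]
  beta0 <- pars[nearest, "beta0"]
  k_vpd <- pars[nearest, "k_vpd"]
  rref <- pars[nearest, "rref"]
  beta <- ifelse(is.finite(d$vpd) & d$vpd > vpd0,
                 beta0 * exp(-k_vpd * (d$vpd - vpd0)), beta0)
  gpp <- (alpha * beta * d$sw_in) / (alpha * d$sw_in + beta)
  gpp[!is.finite(gpp) | d$sw_in <= 0] <- 0
  reco <- rref * lt_shape
  result <- structure(list(timestamp = d$timestamp, reco_pred = reco,
                           gpp_pred = gpp, nee_pred = reco - gpp),
                      class = "partition_result")
  list(result = result, E0 = E0,
       windows = data.frame(center_day = centers, pars,
                            converged = converged))
}
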