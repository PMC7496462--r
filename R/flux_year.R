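#' Half-hourly site-year flux table
#'
#' A `flux_year` bundles one calendar year of half-hourly eddy-covariance and
#' micrometeorological records with site metadata. Columns follow FLUXNET2015
#' FULLSET naming lowered to snake case: `nee` (umol CO2 m-2 s-1), `nee_qc`
#' (0 = measured), `sw_in` (W m-2), `ta` (deg C), `ts` (deg C), `swc` (% vol),
#' `vpd` (hPa), `ws` (m s-1), `wd` (deg, [0, 360)), `precip` (mm per half
#' hour). Timestamps are interval-start local standard time (no DST).
#'
#' @param data data.frame with a POSIXct `timestamp` column plus the flux and
#'   meteorological columns above (missing values as `NA`).
#' @param meta list with `site_id`, `latitude`, `longitude`, `utc_offset`
#'   (hours east of UTC).
#' @param allow_partial accept tables shorter than a full year (toy or
#'   clipped inputs; default `FALSE`). Site-year selection and training
#'   expect full years.
#' @return An object of class `flux_year`: a list with elements `data`
#'   and `meta`.
#' @export
flux_year <- function(data, meta, allow_partial = FALSE) {
  stopifnot(is.data.frame(data), is.list(meta))
  for (f in c("latitude", "longitude", "utc_offset")) {
    if (is.null(meta[[f]])) stop("meta is missing field '", f, "'")
  }
  if (abs(meta$latitude) > 90) stop("latitude out of range")
  if (!"timestamp" %in% names(data)) stop("data has no 'timestamp' column")
  ts <- data$timestamp
  n <- length(ts)
  if (!allow_partial && !(n %in% c(17520L, 17568L))) {
    stop("a flux_year must hold exactly one calendar year of half-hourly ",
         "records (17,520 or 17,568); got ", n,
         " (use allow_partial = TRUE for clipped tables)")
  }
  dt <- diff(as.numeric(ts))
  if (any(dt != 1800)) {
    bad <- which(dt != 1800)[1]
    stop("timestamps must be strictly increasing with a constant 30-min ",
         "step; violated at row ", bad + 1L)
  }
  if (any(data$sw_in < 0, na.rm = TRUE)) stop("sw_in must be >= 0")
  if (!is.null(data$wd) &&
      any(data$wd < 0 | data$wd >= 360, na.rm = TRUE)) {
    stop("wd must lie in [0, 360)")
  }
  if (!is.null(data$swc) &&
      any(data$swc < 0 | data$swc > 100, na.rm = TRUE)) {
    stop("swc must lie in [0, 100]")
  }
  structure(list(data = data, meta = meta), class = "flux_year")
}

#' @export
print.flux_year <- function(x, ...) {
  d <- x$data
  cat(sprintf("<flux_year> %s  lat %.2f lon %.2f  %d records\n",
              x$meta$site_id %||% "?", x$meta$latitude, x$meta$longitude,
              nrow(d)))
  cat(sprintf("  %s .. %s\n", format(d$timestamp[1]),
              format(d$timestamp[nrow(d)])))
  meas <- if (!is.null(d$nee_qc)) mean(d$nee_qc == 0, na.rm = TRUE) else NA
  cat(sprintf("  measured NEE: %.1f%%\n", 100 * meas))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default FLUXNET2015 FULLSET column mapping (target NEE at the median
# u*-threshold of the CUT ensemble).
fluxnet_default_map <- function() {
  c(nee    = "NEE_CUT_USTAR50",
    nee_qc = "NEE_CUT_USTAR50_QC",
    sw_in  = "SW_IN_F",
    ta     = "TA_F",
    ts     = "TS_F_MDS_1",
    swc    = "SWC_F_MDS_1",
    vpd    = "VPD_F",
    ws     = "WS_F",
    wd     = "WD",
    precip = "P_F")
}

#' Read a half-hourly FLUXNET2015-style CSV
#'
#' Reads a comma-separated table in the FLUXNET2015 FULLSET dialect
#' (TIMESTAMP_START in YYYYMMDDHHMM form, -9999 as the missing marker) and
#' returns a validated [flux_year]. Unknown columns are ignored. Columns
#' ending in `_QC` matching a mapped driver are carried along as
#' `<name>_qc` so gap-fill fractions can be assessed.
#'
#' @param path path to the CSV file.
#' @param meta site metadata list (see [flux_year]).
#' @param variable_map named character vector mapping internal names
#'   (`nee`, `sw_in`, ...) to file column names; defaults to the FULLSET
#'   conventions via `fluxnet_default_map()`.
#' @param allow_partial accept files shorter than a full year.
#' @return A [flux_year].
#' @export
read_fluxnet_csv <- function(path, meta, variable_map = NULL,
                             allow_partial = FALSE) {
  map <- fluxnet_default_map()
  if (!is.null(variable_map)) map[names(variable_map)] <- variable_map
  raw <- utils::read.csv(path, check.names = FALSE)
  if (!"TIMESTAMP_START" %in% names(raw)) {
    stop("missing mandatory column TIMESTAMP_START")
  }
  ts <- as.POSIXct(sprintf("%012.0f", as.numeric(raw$TIMESTAMP_START)),
                   format = "%Y%m%d%H%M", tz = "UTC")
  if (anyNA(ts)) {
    stop("unparseable TIMESTAMP_START at row ", which(is.na(ts))[1])
  }
  if (anyDuplicated(ts)) {
    stop("duplicated TIMESTAMP_START at row ", anyDuplicated(ts))
  }
  dt <- diff(as.numeric(ts))
  if (length(dt) && any(dt != 1800)) {
    stop("non-half-hourly cadence at row ", which(dt != 1800)[1] + 1L)
  }
  out <- data.frame(timestamp = ts)
  for (nm in names(map)) {
    col <- map[[nm]]
    if (col %in% names(raw)) {
      v <- as.numeric(raw[[col]])
      v[v == -9999] <- NA_real_
      out[[nm]] <- v
      qc_col <- paste0(col, "_QC")
      if (!endsWith(col, "_QC") && qc_col %in% names(raw) &&
          !nm %in% c("nee")) {
        q <- as.numeric(raw[[qc_col]])
        q[q == -9999] <- NA_real_
        out[[paste0(nm, "_qc")]] <- q
      }
    }
  }
  for (req in c("nee", "sw_in", "ta")) {
    if (is.null(out[[req]])) {
      stop("missing mandatory column ", map[[req]], " (", req, ")")
    }
  }
  flux_year(out, meta, allow_partial = allow_partial)
}

#' Site-year selection criteria
#'
#' Thresholds used to decide whether a site-year is usable for training:
#' at most `max_meteo_gapfill_fraction` of the meteorological driver records
#' gap-filled, and measured NEE covering at least the stated fraction of both
#' daytime and nighttime records.
#'
#' @param max_meteo_gapfill_fraction maximum tolerated mean gap-filled
#'   fraction over the driver variables (default 0.20).
#' @param min_measured_nee_fraction_day,min_measured_nee_fraction_night
#'   minimum fraction of day/night records with measured NEE (default 0.10).
#' @return list of class `selection_criteria`.
#' @export
selection_criteria <- function(max_meteo_gapfill_fraction = 0.20,
                               min_measured_nee_fraction_day = 0.10,
                               min_measured_nee_fraction_night = 0.10) {
  x <- list(max_meteo_gapfill_fraction = max_meteo_gapfill_fraction,
            min_measured_nee_fraction_day = min_measured_nee_fraction_day,
            min_measured_nee_fraction_night = min_measured_nee_fraction_night)
  if (any(unlist(x) < 0 | unlist(x) > 1)) stop("fractions must be in [0,1]")
  class(x) <- "selection_criteria"
  x
}

#' Quality-screen a site-year and build the training mask
#'
#' Computes the three selection fractions (meteorological gap-filled data;
#' measured-NEE coverage of daytime and of nighttime records) and reports
#' pass/fail per criterion. The meteorological gap-filled fraction is the
#' mean over the available driver variables of their per-variable gap-filled
#' flag fractions (a `<var>_qc` value > 0 counts as gap-filled; a variable
#' with no QC column counts as fully measured). No values are altered: the
#' result carries the input table unchanged plus a logical `train_mask`
#' marking records with measured NEE (`nee_qc == 0`).
#'
#' @param fy a [flux_year].
#' @param criteria a [selection_criteria].
#' @param night_threshold_wm2 shortwave threshold separating night from day
#'   (W m-2, default 20).
#' @return list with `table` (the unchanged input), `report` (fractions and
#'   pass/fail flags), and `train_mask`.
#' @export
filter_and_select <- function(fy, criteria = selection_criteria(),
                              night_threshold_wm2 = 20) {
  d <- fy$data
  swpot <- potential_radiation(fy$meta$latitude, fy$meta$longitude,
                               fy$meta$utc_offset, d$timestamp)
  night <- is_night(d$sw_in, sw_in_pot = swpot,
                    threshold = night_threshold_wm2)
  drivers <- c("sw_in", "ta", "ts", "swc", "vpd", "ws")
  fracs <- vapply(drivers, function(nm) {
    if (is.null(d[[nm]])) return(NA_real_)
    qc <- d[[paste0(nm, "_qc")]]
    if (is.null(qc)) 0 else mean(qc > 0, na.rm = TRUE)
  }, numeric(1))
  meteo_gapfill <- mean(fracs, na.rm = TRUE)
  measured <- !is.na(d$nee) & !is.na(d$nee_qc) & d$nee_qc == 0
  frac_day <- mean(measured[!night])
  frac_night <- mean(measured[night])
  report <- list(
    meteo_gapfill_fraction = meteo_gapfill,
    measured_nee_fraction_day = frac_day,
    measured_nee_fraction_night = frac_night,
    pass_meteo = meteo_gapfill <= criteria$max_meteo_gapfill_fraction,
    pass_day = frac_day >= criteria$min_measured_nee_fraction_day,
    pass_night = frac_night >= criteria$min_measured_nee_fraction_night)
  report$pass <- report$pass_meteo && report$pass_day && report$pass_night
  list(table = fy, report = report, train_mask = measured)
}

#' Write a partition result to CSV
#'
#' Writes TIMESTAMP_START plus ensemble-mean NEE/GPP/RECO/LUE predictions and
#' the per-member GPP and RECO columns, at 6 significant digits, so that
#' [read_partition_csv()] round-trips the values.
#'
#' @param result a partition result as returned by [predict_ensemble()] or
#'   the baseline partitioners.
#' @param path output file path.
#' @export
write_partition_csv <- function(result, path) {
  n <- length(result$timestamp)
  out <- data.frame(
    TIMESTAMP_START = format(result$timestamp, "%Y%m%d%H%M"))
  fmt <- function(x) ifelse(is.na(x), "-9999", sprintf("%.6g", x))
  for (nm in c("nee_pred", "gpp_pred", "reco_pred", "lue_pred")) {
    if (!is.null(result[[nm]])) {
      out[[toupper(sub("_pred", "_PRED", nm))]] <- fmt(result[[nm]])
    }
  }
  gm <- result$gpp_members
  rm_ <- result$reco_members
  if (!is.null(gm)) {
    gm <- as.matrix(gm); rm_ <- as.matrix(rm_)
    for (j in seq_len(ncol(gm))) {
      out[[sprintf("GPP_PRED_M%d", j)]] <- fmt(gm[, j])
      out[[sprintf("RECO_PRED_M%d", j)]] <- fmt(rm_[, j])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a partition result written by [write_partition_csv()]
#'
#' @param path CSV path.
#' @return list with `timestamp`, the `*_pred` vectors and member matrices.
#' @export
read_partition_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  num <- function(v) {
    x <- as.numeric(v)
    x[x == -9999] <- NA_real_
    x
  }
  res <- list(timestamp = as.POSIXct(sprintf("%012.0f",
                as.numeric(raw$TIMESTAMP_START)),
                format = "%Y%m%d%H%M", tz = "UTC"))
  for (nm in c("NEE_PRED", "GPP_PRED", "RECO_PRED", "LUE_PRED")) {
    if (nm %in% names(raw)) {
      res[[tolower(sub("_PRED", "_pred", nm))]] <- num(raw[[nm]])
    }
  }
  gcols <- grep("^GPP_PRED_M", names(raw), value = TRUE)
  if (length(gcols)) {
    res$gpp_members <- sapply(gcols, function(cn) num(raw[[cn]]))
    res$reco_members <- sapply(sub("GPP", "RECO", gcols),
                               function(cn) num(raw[[cn]]))
  }
  res
}
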