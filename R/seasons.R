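# Meteorological aggregation, interannual trend fitting, and historical
# tables assembled from profile stacks.

#' Meteorological series tibble
#'
#' @param timestamps POSIXct timestamps, strictly increasing (native cadence
#'   is typically 10 minutes).
#' @param air_temp_c Air temperature, degrees C.
#' @param net_rad_wm2 Net radiation, W m^-2 (optional).
#' @param rain_mm Rainfall per interval, mm (optional, non-negative).
#' @param wind_ms Wind speed, m s^-1 (optional).
#' @return A tibble of class `meteo_series`.
#' @export
meteo_series <- function(timestamps, air_temp_c, net_rad_wm2 = NULL,
                         rain_mm = NULL, wind_ms = NULL) {
  if (any(diff(as.numeric(timestamps)) <= 0)) {
    rlang::abort("Timestamps must be strictly increasing.",
                 class = "meromix_error_domain")
  }
  if (!is.null(rain_mm) && any(rain_mm < 0, na.rm = TRUE)) {
    rlang::abort("Rainfall must be non-negative.",
                 class = "meromix_error_domain")
  }
  cols <- list(timestamp = timestamps, air_temp_c = air_temp_c,
               net_rad_wm2 = net_rad_wm2, rain_mm = rain_mm,
               wind_ms = wind_ms)
  out <- tibble::as_tibble(cols[!vapply(cols, is.null, logical(1))])
  class(out) <- c("meteo_series", class(tibble::tibble()))
  out
}

#' Read a meteo CSV (timestamp, temp_c, netrad_wm2, rain_mm[, wind_ms])
#'
#' @param path File path; `timestamp` must be ISO-8601.
#' @return A `meteo_series` tibble.
#' @export
read_meteo_csv <- function(path) {
  df <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  meteo_series(as.POSIXct(df[["timestamp"]], tz = "UTC"),
               air_temp_c = df[["temp_c"]],
               net_rad_wm2 = df[["netrad_wm2"]],
               rain_mm = df[["rain_mm"]],
               wind_ms = df[["wind_ms"]])
}

native_cadence_s <- function(ts) {
  stats::median(diff(as.numeric(ts)))
}

#' Monthly meteorological summaries
#'
#' Per calendar month: mean and standard deviation of air temperature over
#' the native records, the time-integrated net radiation in J m^-2 (sum of
#' W m^-2 times the record interval in seconds), and the rainfall total in
#' mm. Channels absent from the series yield absent (NA) summary fields.
#' Months whose record count falls below half the expected native-cadence
#' count are flagged `low_coverage` rather than dropped, so instrument
#' outages remain visible.
#'
#' @param series A `meteo_series`.
#' @return A tibble with one row per year-month.
#' @export
monthly_summary <- function(series) {
  stopifnot(nrow(series) >= 1)
  dt <- native_cadence_s(series$timestamp)
  df <- series |>
    dplyr::mutate(year = lubridate::year(.data$timestamp),
                  month = lubridate::month(.data$timestamp))
  has_rad <- !is.null(series[["net_rad_wm2"]])
  has_rain <- !is.null(series[["rain_mm"]])
  df |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      temp_mean_c = mean(.data$air_temp_c, na.rm = TRUE),
      temp_sd_c = stats::sd(.data$air_temp_c, na.rm = TRUE),
      net_radiation_J_m2 = if (has_rad)
        sum(.data$net_rad_wm2 * dt, na.rm = TRUE) else NA_real_,
      rainfall_total_mm = if (has_rain)
        sum(.data$rain_mm, na.rm = TRUE) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      expected_records = lubridate::days_in_month(
        lubridate::make_date(.data$year, .data$month, 1)) * 86400 / dt,
      low_coverage = .data$n_records < 0.5 * .data$expected_records) |>
    dplyr::select(-"expected_records")
}

#' Resample a meteorological series to a coarser window
#'
#' Block means for temperature, radiation and wind; block sums for
#' rainfall; blocks aligned to window starts. A running cumulative-rainfall
#' column is appended, which is the standard companion curve on storm-event
#' plots.
#'
#' @param series A `meteo_series`.
#' @param window Window length in seconds (e.g. `8 * 3600` for 8-hourly,
#'   `86400` for daily). Must be at least the native cadence.
#' @return A `meteo_series`-shaped tibble with an extra `rain_cum_mm`
#'   column when rainfall is present.
#' @export
resample_meteo <- function(series, window) {
  dt <- native_cadence_s(series$timestamp)
  if (window < dt) {
    rlang::abort("Resampling window is finer than the native cadence.",
                 class = "meromix_error_domain")
  }
  origin <- min(series$timestamp)
  block <- floor(as.numeric(series$timestamp - origin, units = "secs") /
                   window)
  out <- series |>
    dplyr::mutate(.block = block) |>
    dplyr::group_by(.data$.block) |>
    dplyr::summarise(
      timestamp = min(.data$timestamp),
      dplyr::across(dplyr::any_of(c("air_temp_c", "net_rad_wm2", "wind_ms")),
                    ~ mean(.x, na.rm = TRUE)),
      dplyr::across(dplyr::any_of("rain_mm"), ~ sum(.x, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::select(-".block")
  if (!is.null(out[["rain_mm"]])) out$rain_cum_mm <- cumsum(out[["rain_mm"]])
  class(out) <- c("meteo_series", class(tibble::tibble()))
  out
}

#' Fit an interannual temperature trend
#'
#' Ordinary least squares of annual mean temperature against calendar year
#' — a descriptive trend line, not a climate attribution analysis. At least
#' three years are required for a reported slope.
#'
#' @param annual_means A data frame with columns `year` and `temp_c` (or a
#'   two-column frame in that order).
#' @return An object of class `annual_trend` with `slope` (degrees C per
#'   year), `intercept`, `n_years` and the underlying [stats::lm()] fit;
#'   supports [generics::tidy()] and [generics::glance()].
#' @export
annual_trend <- function(annual_means) {
  df <- tibble::as_tibble(annual_means)
  if (!all(c("year", "temp_c") %in% names(df)) && ncol(df) >= 2) {
    names(df)[1:2] <- c("year", "temp_c")
  }
  df <- dplyr::filter(df, is.finite(.data$year), is.finite(.data$temp_c))
  if (dplyr::n_distinct(df$year) < 3) {
    rlang::abort("At least 3 distinct years are needed for a trend.",
                 class = "meromix_error_insufficient_data")
  }
  fit <- stats::lm(temp_c ~ year, data = df)
  structure(list(slope = unname(stats::coef(fit)[["year"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 n_years = dplyr::n_distinct(df$year),
                 fit = fit),
            class = "annual_trend")
}

#' @export
print.annual_trend <- function(x, ...) {
  cat(sprintf("Interannual trend: %+.4f degC/year over %d years\n",
              x$slope, x$n_years))
  invisible(x)
}

#' Historical record table from a stack of casts
#'
#' One row per cast: surface and bottom temperature and k20 (surface =
#' mean over the shallowest `surface_window` metres of the cast, bottom =
#' mean over the deepest `bottom_window` metres), Schmidt stability when
#' supplied, and bottom hydrogen sulfide as the mean of observations within
#' `h2s_range` (default 18-20 m, inclusive). Casts shallower than 2 m are
#' skipped with a message. Aggregate per-cast rows to yearly mean +/- sd
#' with [summarize_yearly()].
#'
#' @param profiles List of QC'd `ctd_profile` objects with `k20_uScm` (or
#'   raw conductivity, normalised on the fly).
#' @param stability Optional tibble with `cast_id` and `sc_kJ_m2` (e.g.
#'   from [stability_series()]).
#' @param h2s_obs Optional tibble of sulfide observations with `cast_id`,
#'   `depth_m`, `h2s_mgL`.
#' @param surface_window,bottom_window Extraction windows in metres.
#' @param h2s_range Depth range (inclusive) defining "lake bottom" for
#'   sulfide.
#' @return A tibble with one row per retained cast.
#' @export
historical_record_table <- function(profiles, stability = NULL,
                                    h2s_obs = NULL,
                                    surface_window = 0.5, bottom_window = 1,
                                    h2s_range = c(18, 20)) {
  rows <- purrr::map(profiles, function(p) {
    z <- p$depth_m
    if (max(z) - min(z) < 2) {
      rlang::inform(sprintf("Skipping cast '%s': shallower than 2 m.",
                            attr(p, "cast_id")))
      return(NULL)
    }
    if (is.null(p[["k20_uScm"]]) && !is.null(p[["cond_raw_uScm"]])) p <- add_k20(p)
    surf <- z <= min(z) + surface_window
    bot <- z >= max(z) - bottom_window
    ts <- attr(p, "timestamp")
    tibble::tibble(
      cast_id = attr(p, "cast_id") %||% "cast",
      date = if (inherits(ts, c("Date", "POSIXct"))) as.Date(ts)
             else as.Date(NA),
      surface_temp_c = mean(p[["temp_c"]][surf]),
      bottom_temp_c = mean(p[["temp_c"]][bot]),
      surface_k20_uScm = if (!is.null(p[["k20_uScm"]]))
        mean(p[["k20_uScm"]][surf]) else NA_real_,
      bottom_k20_uScm = if (!is.null(p[["k20_uScm"]]))
        mean(p[["k20_uScm"]][bot]) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  if (!is.null(stability)) {
    out <- dplyr::left_join(out,
                            dplyr::select(tibble::as_tibble(stability),
                                          "cast_id", "sc_kJ_m2"),
                            by = "cast_id")
  }
  if (!is.null(h2s_obs)) {
    h2s <- tibble::as_tibble(h2s_obs) |>
      dplyr::filter(.data$depth_m >= h2s_range[1],
                    .data$depth_m <= h2s_range[2]) |>
      dplyr::group_by(.data$cast_id) |>
      dplyr::summarise(bottom_h2s_mgL = mean(.data$h2s_mgL),
                       .groups = "drop")
    out <- dplyr::left_join(out, h2s, by = "cast_id")
  }
  out
}

#' Yearly mean and standard deviation of historical records
#'
#' @param records A per-cast tibble from [historical_record_table()] (or
#'   any tibble with a `date` column and numeric value columns).
#' @return A tibble with one row per year and `<var>_mean` / `<var>_sd`
#'   columns for each numeric variable.
#' @export
summarize_yearly <- function(records) {
  records |>
    dplyr::mutate(year = lubridate::year(.data$date)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_casts = dplyr::n(),
      dplyr::across(dplyr::where(is.numeric) & !dplyr::any_of("year"),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ stats::sd(.x, na.rm = TRUE))),
      .groups = "drop")
}
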