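# CTD cast ingestion, quality control and standardisation.

#' Construct a CTD profile tibble
#'
#' A CTD profile is a tibble with one row per depth sample and canonical
#' column names (`depth_m`, `temp_c`, `cond_raw_uScm`, `k20_uScm`, `do_mgL`,
#' `turb_ftu`, `bgapc_ppb`, `par`). Optional channels may be absent entirely;
#' they are never padded with placeholder values. Cast identity and time are
#' carried as attributes so the table itself stays purely numeric.
#'
#' @param depth_m Depth grid in metres, positive downward, strictly increasing.
#' @param temp_c Temperature in degrees Celsius, same length as `depth_m`.
#' @param cond_raw_uScm In-situ conductivity in uS/cm (optional).
#' @param k20_uScm Conductivity normalised to 20 degrees C (optional; see
#'   [normalize_conductivity_k20()]).
#' @param do_mgL Dissolved oxygen in mg/l (optional, must be non-negative).
#' @param turb_ftu Turbidity in formazine turbidity units (optional,
#'   non-negative).
#' @param bgapc_ppb Phycocyanin fluorescence in ppb (optional).
#' @param par Photosynthetically active radiation (optional).
#' @param cast_id Identifier for the cast.
#' @param timestamp Date-time of the cast (anything `as.POSIXct` accepts).
#' @param z_bot_max Maximum admissible depth in metres (default 21; the
#'   morphometric table of the study site lists 21.5 m while the stability
#'   integral uses a 21 m bottom — the stricter value is the default and can
#'   be relaxed per cast).
#'
#' @return A tibble of class `ctd_profile`.
#' @export
ctd_profile <- function(depth_m, temp_c,
                        cond_raw_uScm = NULL, k20_uScm = NULL,
                        do_mgL = NULL, turb_ftu = NULL,
                        bgapc_ppb = NULL, par = NULL,
                        cast_id = "cast", timestamp = NA,
                        z_bot_max = 21) {
  cols <- list(depth_m = depth_m, temp_c = temp_c,
               cond_raw_uScm = cond_raw_uScm, k20_uScm = k20_uScm,
               do_mgL = do_mgL, turb_ftu = turb_ftu,
               bgapc_ppb = bgapc_ppb, par = par)
  cols <- cols[!vapply(cols, is.null, logical(1))]
  out <- tibble::as_tibble(cols)
  out <- new_ctd_profile(out, cast_id = cast_id, timestamp = timestamp)
  validate_ctd_profile(out, z_bot_max = z_bot_max)
}

new_ctd_profile <- function(df, cast_id = "cast", timestamp = NA) {
  out <- tibble::as_tibble(df)
  attr(out, "cast_id") <- as.character(cast_id)
  attr(out, "timestamp") <- timestamp
  class(out) <- c("ctd_profile", class(tibble::tibble()))
  out
}

validate_ctd_profile <- function(profile, z_bot_max = 21) {
  z <- profile$depth_m
  if (is.null(z)) {
    rlang::abort("`depth_m` column is required.", class = "meromix_error_schema")
  }
  if (any(!is.finite(z))) {
    rlang::abort("Depths must be finite.", class = "meromix_error_domain")
  }
  if (any(diff(z) <= 0)) {
    rlang::abort("Depths must be strictly increasing.",
                 class = "meromix_error_domain")
  }
  if (min(z) < 0 || max(z) > z_bot_max) {
    rlang::abort(
      sprintf("Depths must lie in [0, %g] m (observed %.3g-%.3g).",
              z_bot_max, min(z), max(z)),
      class = "meromix_error_domain")
  }
  if (!is.null(profile[["turb_ftu"]]) &&
      any(profile[["turb_ftu"]] < 0, na.rm = TRUE)) {
    rlang::abort("Turbidity must be non-negative.",
                 class = "meromix_error_domain")
  }
  if (!is.null(profile[["do_mgL"]]) && any(profile[["do_mgL"]] < 0, na.rm = TRUE)) {
    rlang::abort("Dissolved oxygen must be non-negative.",
                 class = "meromix_error_domain")
  }
  profile
}

#' @export
print.ctd_profile <- function(x, ...) {
  cat(sprintf("# CTD profile '%s' (%d samples, %.2f-%.2f m)\n",
              attr(x, "cast_id"), nrow(x), min(x$depth_m), max(x$depth_m)))
  NextMethod()
}

# conversion used when a cast reports pressure rather than depth:
# 1 mbar of excess pressure ~ 0.010197 m of fresh water (g = 9.81 m s^-2)
MBAR_TO_M <- 0.010197

#' Parse a delimited CTD cast export into a profile
#'
#' Reads an instrument export (comma- or tab-delimited text with a header
#' row, or an already-loaded data frame) and maps its columns onto the
#' canonical profile schema. Rows are sorted by increasing depth and
#' duplicate depths are collapsed by averaging, so up/down-cast mixtures and
#' shuffled exports yield the same profile. With `downcast_only = TRUE` only
#' the leading monotone-increasing segment of the raw cast (the downcast) is
#' kept before sorting.
#'
#' @param source Path to a delimited text file, or a data frame.
#' @param column_map Named character vector mapping canonical names
#'   (`depth`, `pressure`, `temperature`, `conductivity`, `k20`, `oxygen`,
#'   `turbidity`, `bgapc`, `par`) to the source's column names. `depth` (or
#'   `pressure` with `pressure_mode = TRUE`), `temperature` and
#'   `conductivity` are required.
#' @param pressure_mode If `TRUE`, depth is derived from a pressure column in
#'   mbar as `0.010197 * (p - surface_offset_mbar)`.
#' @param surface_offset_mbar Pressure at the surface; defaults to the
#'   minimum pressure observed in the cast (the probe's shallowest sample).
#' @param downcast_only Keep only the first monotone-increasing depth
#'   segment of the raw record before sorting.
#' @param cast_id,timestamp,z_bot_max Passed to [ctd_profile()].
#'
#' @return A `ctd_profile` tibble sorted by increasing depth.
#' @export
parse_ctd_table <- function(source, column_map,
                            pressure_mode = FALSE,
                            surface_offset_mbar = NULL,
                            downcast_only = FALSE,
                            cast_id = "cast", timestamp = NA,
                            z_bot_max = 21) {
  raw <- read_delim_table(source)
  need <- c(if (pressure_mode) "pressure" else "depth",
            "temperature", "conductivity")
  missing_keys <- setdiff(need, names(column_map))
  if (length(missing_keys) > 0) {
    rlang::abort(
      paste0("column_map lacks required entries: ",
             paste(missing_keys, collapse = ", ")),
      class = "meromix_error_schema")
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0) {
    rlang::abort(
      paste0("Source is missing mapped column(s): ",
             paste(absent, collapse = ", ")),
      class = "meromix_error_schema")
  }
  if (nrow(raw) < 3) {
    rlang::abort("A cast needs at least 3 samples.",
                 class = "meromix_error_insufficient_data")
  }

  num <- function(key) {
    if (!key %in% names(column_map)) return(NULL)
    as_numeric_checked(raw[[column_map[[key]]]], column_map[[key]])
  }

  depth <- if (pressure_mode) {
    p <- num("pressure")
    off <- surface_offset_mbar %||% min(p)
    MBAR_TO_M * (p - off)
  } else {
    num("depth")
  }

  df <- tibble::tibble(
    depth_m = depth,
    temp_c = num("temperature"),
    cond_raw_uScm = num("conductivity"))
  opt <- c(k20 = "k20_uScm", oxygen = "do_mgL", turbidity = "turb_ftu",
           bgapc = "bgapc_ppb", par = "par")
  for (key in names(opt)) {
    v <- num(key)
    if (!is.null(v)) df[[opt[[key]]]] <- v
  }

  if (downcast_only && any(diff(df$depth_m) <= 0)) {
    k <- which(diff(df$depth_m) <= 0)[1]
    df <- df[seq_len(k), , drop = FALSE]
  }

  df <- df |>
    dplyr::arrange(.data$depth_m) |>
    dplyr::group_by(.data$depth_m) |>
    dplyr::summarise(dplyr::across(dplyr::everything(),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")

  out <- new_ctd_profile(df, cast_id = cast_id, timestamp = timestamp)
  validate_ctd_profile(out, z_bot_max = z_bot_max)
}

read_delim_table <- function(source) {
  if (is.data.frame(source)) return(tibble::as_tibble(source))
  first <- readLines(source, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(source, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
}

as_numeric_checked <- function(x, colname) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & trimws(x) != "" &
                 !toupper(trimws(x)) %in% c("NA", "NAN"))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("Non-numeric value '%s' in column '%s', row %d.",
              x[bad[1]], colname, bad[1]),
      class = "meromix_error_parse")
  }
  v
}

#' Normalise conductivity to the 20 degree C reference
#'
#' In-situ conductivity increases with temperature; dissolved-ion content is
#' therefore compared through the conductivity the same water would show at
#' 20 degrees C. The linear temperature-compensation model used by most
#' limnological probes is applied:
#' `k20 = k_T / (1 + alpha_t * (T - 20))`,
#' with a default compensation coefficient of 2 percent per degree C.
#'
#' @param conductivity_raw In-situ conductivity, uS/cm (non-negative).
#' @param temperature Water temperature, degrees C.
#' @param alpha_t Temperature-compensation coefficient per degree C, in
#'   (0, 0.1); default 0.020.
#'
#' @return Conductivity at the 20 degree C reference, uS/cm.
#' @export
normalize_conductivity_k20 <- function(conductivity_raw, temperature,
                                       alpha_t = 0.020) {
  if (alpha_t <= 0 || alpha_t >= 0.1) {
    rlang::abort("alpha_t must lie in (0, 0.1).",
                 class = "meromix_error_domain")
  }
  if (any(conductivity_raw < 0, na.rm = TRUE)) {
    rlang::abort("Conductivity must be non-negative.",
                 class = "meromix_error_domain")
  }
  denom <- 1 + alpha_t * (temperature - 20)
  if (any(denom <= 0, na.rm = TRUE)) {
    rlang::abort(
      "Temperature below the compensation model's domain (denominator <= 0).",
      class = "meromix_error_domain")
  }
  conductivity_raw / denom
}

#' Add the normalised-conductivity channel to a profile
#'
#' @param profile A `ctd_profile` with `cond_raw_uScm` and `temp_c`.
#' @param alpha_t Compensation coefficient, see
#'   [normalize_conductivity_k20()].
#' @return The profile with a `k20_uScm` column.
#' @export
add_k20 <- function(profile, alpha_t = 0.020) {
  if (is.null(profile[["cond_raw_uScm"]])) {
    rlang::abort("Profile has no raw-conductivity channel.",
                 class = "meromix_error_missing_channel")
  }
  profile[["k20_uScm"]] <- normalize_conductivity_k20(
    profile[["cond_raw_uScm"]], profile$temp_c, alpha_t)
  profile
}

#' Despike and regrid a CTD profile
#'
#' Each channel is run through a running-median despiking filter
#' ([stats::runmed()]) and then linearly interpolated onto a uniform depth
#' grid spanning the observed depth range. No extrapolation is performed:
#' the grid runs from the shallowest to the deepest observed sample.
#'
#' @param profile A `ctd_profile`.
#' @param grid_step Target grid spacing in metres (default 0.1).
#' @param despike_window Odd window length for the running median (default
#'   5; 1 disables despiking).
#' @return A `ctd_profile` on the uniform grid.
#' @export
qc_and_regrid <- function(profile, grid_step = 0.1, despike_window = 5) {
  stopifnot(grid_step > 0)
  if (despike_window %% 2 != 1) {
    rlang::abort("despike_window must be odd.", class = "meromix_error_domain")
  }
  z <- profile$depth_m
  span <- max(z) - min(z)
  if (grid_step > span) {
    rlang::abort("Grid step exceeds the cast's depth span.",
                 class = "meromix_error_insufficient_data")
  }
  grid <- seq(min(z), max(z), by = grid_step)

  channels <- setdiff(names(profile), "depth_m")
  out <- tibble::tibble(depth_m = grid)
  for (ch in channels) {
    v <- profile[[ch]]
    if (despike_window > 1 && length(v) >= despike_window) {
      v <- as.numeric(stats::runmed(v, despike_window, endrule = "median"))
    }
    out[[ch]] <- stats::approx(z, v, xout = grid, ties = "ordered")$y
  }
  new_ctd_profile(out,
                  cast_id = attr(profile, "cast_id"),
                  timestamp = attr(profile, "timestamp"))
}

#' Write / read the canonical profile CSV
#'
#' The canonical on-disk form is a plain CSV with the fixed column names of
#' [ctd_profile()]; cast id and timestamp travel in `# key: value` comment
#' headers so a round trip preserves them.
#'
#' @param profile A `ctd_profile`.
#' @param path File path.
#' @return `write_ctd_csv` returns `path` invisibly; `read_ctd_csv` returns
#'   a `ctd_profile`.
#' @export
write_ctd_csv <- function(profile, path) {
  ts <- attr(profile, "timestamp")
  hdr <- c(sprintf("# cast_id: %s", attr(profile, "cast_id")),
           sprintf("# timestamp: %s", format(ts)))
  body <- utils::capture.output(
    utils::write.csv(as.data.frame(profile), row.names = FALSE))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ctd_csv
#' @export
read_ctd_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(m) == 0) return(NA)
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")])
  ts <- get_meta("timestamp")
  if (!is.na(ts) && ts != "NA") ts <- as.POSIXct(ts, tz = "UTC") else ts <- NA
  new_ctd_profile(tibble::as_tibble(df),
                  cast_id = get_meta("cast_id"), timestamp = ts)
}
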