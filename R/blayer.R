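# Turbidity-based detection of the anoxygenic phototroph bacterial layer,
# sampling-depth planning and isotherm/oxycline tracking.

#' Detect the bacterial layer from a turbidity profile
#'
#' The dense stratum of phototrophic sulfur bacteria in the lower chemocline
#' shows up as a strong turbidity peak; a sustained excursion above a fixed
#' threshold (default 10 FTU) is taken as its physical signature. The
#' profile is scanned for maximal contiguous intervals with turbidity
#' strictly above the threshold; interval boundaries are refined by linear
#' interpolation of the threshold crossing between neighbouring samples, so
#' the reported top/bottom do not snap to the sampling grid. When several
#' intervals survive the minimum-thickness filter, the one containing the
#' global turbidity maximum is returned (`select = "deepest"` picks the
#' deepest interval instead).
#'
#' @param profile A `ctd_profile` with a `turb_ftu` channel.
#' @param threshold Turbidity threshold in FTU (default 10).
#' @param min_thickness Minimum interval thickness in metres (default 0.1);
#'   rejects single-sample spikes that despiking missed.
#' @param select Tie-break among multiple super-threshold intervals:
#'   `"global_max"` (default) or `"deepest"`.
#' @return A one-row tibble (`cast_id`, `top_m`, `bottom_m`, `thickness_m`,
#'   `peak_depth_m`, `peak_turb_ftu`, `threshold_ftu`), or `NULL` when no
#'   interval survives.
#' @export
detect_bacterial_layer <- function(profile, threshold = 10,
                                   min_thickness = 0.1,
                                   select = c("global_max", "deepest")) {
  select <- match.arg(select)
  stopifnot(threshold > 0, min_thickness >= 0)
  turb <- profile[["turb_ftu"]]
  if (is.null(turb)) {
    rlang::abort("Profile has no turbidity channel.",
                 class = "meromix_error_missing_channel")
  }
  z <- profile$depth_m
  above <- turb > threshold
  if (!any(above)) return(NULL)

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  idx <- which(runs$values)

  cross <- function(i1, i2) {
    # depth where turbidity crosses the threshold between samples i1, i2
    z[i1] + (threshold - turb[i1]) / (turb[i2] - turb[i1]) * (z[i2] - z[i1])
  }

  intervals <- purrr::map_dfr(idx, function(k) {
    s <- starts[k]; e <- ends[k]
    top <- if (s == 1) z[1] else cross(s - 1, s)
    bottom <- if (e == length(z)) z[length(z)] else cross(e, e + 1)
    pk <- s - 1 + which.max(turb[s:e])
    tibble::tibble(top_m = top, bottom_m = bottom,
                   thickness_m = bottom - top,
                   peak_depth_m = z[pk], peak_turb_ftu = turb[pk])
  })
  intervals <- dplyr::filter(intervals, .data$thickness_m >= min_thickness)
  if (nrow(intervals) == 0) return(NULL)

  pick <- if (select == "global_max") {
    which.max(intervals$peak_turb_ftu)
  } else {
    which.max(intervals$bottom_m)
  }
  dplyr::bind_cols(
    tibble::tibble(cast_id = attr(profile, "cast_id") %||% "cast"),
    intervals[pick, ],
    tibble::tibble(threshold_ftu = threshold))
}

#' Plan the five bacterial-layer sampling depths
#'
#' Sampling targets the layer and its immediate surroundings: 1 m above the
#' layer, at its top, 50 cm inside, at its bottom, and 1 m below. Depths
#' falling outside the water column are clipped to `[0, z_bot]` and flagged.
#'
#' @param bl A detected bacterial layer (one-row tibble from
#'   [detect_bacterial_layer()]).
#' @param z_bot Bottom depth in metres (default 21).
#' @return A five-row tibble with `label`, `depth_m` and `clipped`.
#' @export
plan_sampling_depths <- function(bl, z_bot = 21) {
  raw <- c(above_1m = bl$top_m - 1.0,
           bl_top = bl$top_m,
           bl_mid_50cm = bl$top_m + 0.5,
           bl_bottom = bl$bottom_m,
           below_1m = bl$bottom_m + 1.0)
  clipped <- pmin(pmax(raw, 0), z_bot)
  tibble::tibble(label = names(raw),
                 depth_m = unname(clipped),
                 clipped = unname(clipped != raw))
}

first_crossing <- function(z, v, target, direction = c("any", "down")) {
  # shallowest linearly interpolated depth where v crosses `target`;
  # direction = "down" requires v to fall from >= target to < target
  direction <- match.arg(direction)
  ok <- is.finite(v)
  z <- z[ok]; v <- v[ok]
  if (length(z) < 2) return(NA_real_)
  if (direction == "down" && v[1] < target) return(z[1])
  for (i in seq_len(length(z) - 1)) {
    v1 <- v[i]; v2 <- v[i + 1]
    hit <- if (direction == "down") v1 >= target && v2 < target
           else (v1 - target) * (v2 - target) <= 0
    if (hit) {
      if (v1 == target) return(z[i])
      if (v1 == v2) next
      return(z[i] + (target - v1) / (v2 - v1) * (z[i + 1] - z[i]))
    }
  }
  NA_real_
}

#' Depth of an isotherm
#'
#' Shallowest depth at which the temperature profile crosses `t_iso`,
#' linearly interpolated between samples; `NA` if never crossed.
#'
#' @param profile A `ctd_profile` with `temp_c`.
#' @param t_iso Isotherm temperature in degrees C (e.g. 10 or 5, the two
#'   isotherms conventionally overlaid on seasonal section plots).
#' @return Depth in metres, or `NA`.
#' @export
isotherm_depth <- function(profile, t_iso) {
  first_crossing(profile$depth_m, profile$temp_c, t_iso, "any")
}

#' Depth of the oxycline
#'
#' Shallowest linearly interpolated depth where dissolved oxygen falls below
#' `do_threshold` — a practical marker for the top of the anoxic zone. The
#' threshold is a tunable convention (default 0.5 mg/l).
#'
#' @param profile A `ctd_profile` with `do_mgL`.
#' @param do_threshold Dissolved-oxygen threshold in mg/l (> 0).
#' @return Depth in metres, or `NA` when oxygen never falls below the
#'   threshold.
#' @export
oxycline_depth <- function(profile, do_threshold = 0.5) {
  stopifnot(do_threshold > 0)
  if (is.null(profile[["do_mgL"]])) {
    rlang::abort("Profile has no dissolved-oxygen channel.",
                 class = "meromix_error_missing_channel")
  }
  first_crossing(profile$depth_m, profile[["do_mgL"]], do_threshold, "down")
}

#' Seasonal series of bacterial-layer geometry
#'
#' Runs [detect_bacterial_layer()] over a stack of casts and assembles a
#' chronologically sorted series of layer top/bottom/thickness. Casts in
#' which no layer is detected are kept as gap rows (all-NA geometry) so the
#' series' time base stays complete. `above_13_5` records whether the whole
#' layer sits above 13.5 m, the depth horizon conventionally drawn on
#' seasonal layer plots.
#'
#' @param profiles A list of `ctd_profile` objects with turbidity channels
#'   and `timestamp` attributes.
#' @param threshold Turbidity threshold in FTU.
#' @param ... Passed to [detect_bacterial_layer()].
#' @return A tibble with `cast_id`, `date`, `top_m`, `bottom_m`,
#'   `thickness_m`, `peak_turb_ftu`, `above_13_5`.
#' @export
bl_season_series <- function(profiles, threshold = 10, ...) {
  if (length(profiles) == 0) {
    return(tibble::tibble(cast_id = character(), date = as.Date(character()),
                          top_m = double(), bottom_m = double(),
                          thickness_m = double(), peak_turb_ftu = double(),
                          above_13_5 = logical()))
  }
  rows <- purrr::map_dfr(profiles, function(p) {
    ts <- attr(p, "timestamp")
    date <- if (inherits(ts, c("Date", "POSIXct"))) as.Date(ts) else as.Date(NA)
    bl <- detect_bacterial_layer(p, threshold = threshold, ...)
    if (is.null(bl)) {
      tibble::tibble(cast_id = attr(p, "cast_id") %||% "cast", date = date,
                     top_m = NA_real_, bottom_m = NA_real_,
                     thickness_m = NA_real_, peak_turb_ftu = NA_real_,
                     above_13_5 = NA)
    } else {
      tibble::tibble(cast_id = bl$cast_id, date = date,
                     top_m = bl$top_m, bottom_m = bl$bottom_m,
                     thickness_m = bl$thickness_m,
                     peak_turb_ftu = bl$peak_turb_ftu,
                     above_13_5 = bl$bottom_m < 13.5)
    }
  })
  dplyr::arrange(rows, .data$date)
}
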