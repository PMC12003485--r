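# Density equation of state and Schmidt stability over a hypsometric curve.

#' Density equation-of-state parameters
#'
#' Freshwater density is modelled as a cubic in temperature plus a linear
#' salinity term, `rho_w(T, S) = rho'_w(T) + beta * S`, with
#' `rho'_w(T) = a0 + a1 T + a2 T^2 + a3 T^3` and salinity obtained from
#' 20-degree-normalised conductivity as `S = alpha_s * k20` (kg m^-3). The
#' defaults are the ion-specific calibration for an alpine crenogenic
#' meromictic lake whose monimolimnion salinity is dominated by sulfate and
#' bicarbonate.
#'
#' The haline contraction coefficient is published as 0.96e-3 kg/g; with
#' salinity expressed in kg m^-3 (i.e. g/l) the dimensionless equivalent is
#' 0.96, which is the default here — it yields the ~0.3 kg m^-3 density
#' excess across the chemocline that sustains meromixis. Pass
#' `beta = 0.96e-3` to use the literal printed value instead.
#'
#' @param a0,a1,a2,a3 Cubic coefficients of the pure-water density
#'   polynomial (kg m^-3 per degree C power).
#' @param beta Haline contraction coefficient (dimensionless under the
#'   default unit resolution).
#' @param alpha_s Conductivity-to-salinity factor, kg m^-3 per uS/cm.
#' @return A list of class `density_params`.
#' @export
density_params <- function(a0 = 999.84, a1 = 6.55e-2, a2 = -8.56e-3,
                           a3 = 5.94e-5, beta = 0.96, alpha_s = 0.72e-3) {
  stopifnot(a0 > 900, alpha_s > 0, beta > 0)
  structure(list(a0 = a0, a1 = a1, a2 = a2, a3 = a3,
                 beta = beta, alpha_s = alpha_s),
            class = "density_params")
}

#' Salinity from normalised conductivity
#'
#' @param k20 Conductivity normalised to 20 degrees C, uS/cm (non-negative).
#' @param params A [density_params()] object.
#' @return Salinity in kg m^-3.
#' @export
salinity_from_k20 <- function(k20, params = density_params()) {
  if (any(k20 < 0, na.rm = TRUE)) {
    rlang::abort("k20 must be non-negative.", class = "meromix_error_domain")
  }
  params$alpha_s * k20
}

#' Water density from temperature and normalised conductivity
#'
#' @param temperature Temperature in degrees C, within [-2, 40].
#' @param k20 Conductivity normalised to 20 degrees C, uS/cm.
#' @param params A [density_params()] object.
#' @return Density in kg m^-3.
#' @export
water_density <- function(temperature, k20 = 0, params = density_params()) {
  if (any(temperature < -2 | temperature > 40, na.rm = TRUE)) {
    rlang::abort("Temperature outside the model's [-2, 40] degree C range.",
                 class = "meromix_error_domain")
  }
  rho_t <- params$a0 + params$a1 * temperature +
    params$a2 * temperature^2 + params$a3 * temperature^3
  rho_t + params$beta * salinity_from_k20(k20, params)
}

#' Density profile from a CTD cast
#'
#' @param profile A `ctd_profile` carrying `temp_c` and `k20_uScm` (compute
#'   the latter with [add_k20()] if only raw conductivity is present).
#' @param params A [density_params()] object.
#' @return A tibble with `depth_m`, `salinity_kg_m3` and `density_kg_m3`.
#' @export
density_profile <- function(profile, params = density_params()) {
  if (is.null(profile[["k20_uScm"]])) {
    rlang::abort("Profile has no k20 channel; run add_k20() first.",
                 class = "meromix_error_missing_channel")
  }
  tibble::tibble(
    depth_m = profile$depth_m,
    salinity_kg_m3 = salinity_from_k20(profile[["k20_uScm"]], params),
    density_kg_m3 = water_density(profile$temp_c, profile[["k20_uScm"]], params))
}

#' Parametric power-law hypsometry
#'
#' When the measured area-depth curve of a basin is unavailable, a one-
#' parameter power law `A(z) = A_o (1 - z / z_bot)^q` is a standard stand-in:
#' `q = 0` is a box (vertical-walled) lake, `q = 1` a cone-like basin, and
#' intermediate exponents interpolate bowl shapes. Its centre of volume has
#' the closed form `z_bot / (q + 2)`, which makes it a convenient oracle for
#' the quadrature-based [center_of_volume()].
#'
#' @param A_o Surface area in m^2 (default 0.23e6).
#' @param z_bot Bottom depth in metres (default 21).
#' @param q Shape exponent (>= 0; default 1.96, which reproduces a 5.3 m
#'   centre of volume for a 21 m deep basin).
#' @param n Number of uniformly spaced depths (default 211).
#' @return A tibble of class `hypsometry` with `depth_m` and `area_m2`.
#' @export
parametric_hypsometry <- function(A_o = 0.23e6, z_bot = 21, q = 1.96,
                                  n = 211) {
  stopifnot(A_o > 0, z_bot > 0, q >= 0, n >= 2)
  z <- seq(0, z_bot, length.out = n)
  new_hypsometry(tibble::tibble(depth_m = z,
                                area_m2 = A_o * (1 - z / z_bot)^q))
}

new_hypsometry <- function(df) {
  out <- tibble::as_tibble(df)
  z <- out$depth_m
  a <- out$area_m2
  if (is.null(z) || is.null(a)) {
    rlang::abort("Hypsometry needs depth_m and area_m2 columns.",
                 class = "meromix_error_schema")
  }
  if (z[1] != 0 || any(diff(z) <= 0)) {
    rlang::abort("Hypsometry depths must start at 0 and increase strictly.",
                 class = "meromix_error_domain")
  }
  if (any(a < 0) || a[1] <= 0 || any(diff(a) > 1e-9 * a[1])) {
    rlang::abort("Areas must be non-negative and non-increasing with depth.",
                 class = "meromix_error_domain")
  }
  class(out) <- c("hypsometry", class(tibble::tibble()))
  out
}

#' Read a two-column hypsometry CSV (depth_m, area_m2)
#'
#' @param path File path.
#' @return A `hypsometry` tibble.
#' @export
read_hypsometry <- function(path) {
  new_hypsometry(readr::read_csv(path, col_types = "dd", progress = FALSE))
}

#' Depth of the basin's centre of volume
#'
#' `z_v = int z A(z) dz / int A(z) dz`, evaluated by trapezoidal quadrature
#' on the hypsometry's own grid.
#'
#' @param hyps A `hypsometry` tibble.
#' @return Centre-of-volume depth in metres.
#' @export
center_of_volume <- function(hyps) {
  vol <- pracma::trapz(hyps$depth_m, hyps$area_m2)
  if (vol <= 0) {
    rlang::abort("Hypsometry encloses zero volume.",
                 class = "meromix_error_degenerate")
  }
  pracma::trapz(hyps$depth_m, hyps$depth_m * hyps$area_m2) / vol
}

#' Schmidt stability of a density-stratified water column
#'
#' The Schmidt stability index Sc is the mechanical work per unit surface
#' area needed to mix the water column to uniform density:
#' `Sc = (1 / A_o) * int_0^z_bot g rho_w(z) (z - z_v) A(z) dz`,
#' with `g = 9.81 m s^-2`, `A_o` the surface area and `A(z)` the hypsometric
#' curve. Two conventions for the reference depth `z_v` are supported:
#'
#' * `"as_printed"` (default) uses a fixed `z_v` (default 5.3 m, the
#'   published centre-of-volume depth for this basin). When the fixed value
#'   is not the exact discrete centre of volume of the hypsometry in use,
#'   the full density (not just its anomaly) contributes a constant offset.
#' * `"anomaly"` recomputes `z_v` as the centre of volume on the quadrature
#'   grid, which makes Sc exactly invariant to adding a constant to the
#'   density profile and non-negative for gravitationally stable profiles.
#'
#' The density profile is interpolated onto a uniform quadrature grid over
#' `[0, z_bot]`; beyond the observed depth range the shallowest/deepest
#' density values are extended as constants (flagged in the result), since
#' casts rarely reach exactly the surface or the bottom.
#'
#' @param density_profile A tibble with `depth_m` and `density_kg_m3`
#'   (e.g. from [density_profile()]).
#' @param hyps A `hypsometry` tibble.
#' @param mode `"as_printed"` or `"anomaly"`.
#' @param z_v_fixed Reference depth for `"as_printed"` mode, metres.
#' @param grid_step Quadrature grid spacing in metres (default 0.1).
#' @param g Gravitational acceleration, m s^-2.
#' @return A one-row tibble of class `stability_result` with `sc_J_m2`,
#'   `sc_kJ_m2`, `z_v_used`, `mode`, `n_grid` and an `extrapolated` flag.
#' @export
schmidt_stability <- function(density_profile, hyps,
                              mode = c("as_printed", "anomaly"),
                              z_v_fixed = 5.3, grid_step = 0.1, g = 9.81) {
  mode <- match.arg(mode)
  z_bot <- max(hyps$depth_m)
  if (mode == "as_printed" && (z_v_fixed < 0 || z_v_fixed > z_bot)) {
    rlang::abort("z_v_fixed must lie within [0, z_bot].",
                 class = "meromix_error_domain")
  }
  zp <- density_profile$depth_m
  rho <- density_profile$density_kg_m3
  if (length(zp) < 2 || any(diff(zp) <= 0)) {
    rlang::abort("Density profile needs strictly increasing depths.",
                 class = "meromix_error_grid")
  }

  grid <- seq(0, z_bot, by = grid_step)
  if (grid[length(grid)] < z_bot) grid <- c(grid, z_bot)
  # rule = 2: constant extension of the end values to the boundaries
  rho_g <- stats::approx(zp, rho, xout = grid, rule = 2, ties = "ordered")$y
  area_g <- stats::approx(hyps$depth_m, hyps$area_m2, xout = grid,
                          rule = 2, ties = "ordered")$y
  extrapolated <- min(zp) > 0 || max(zp) < z_bot

  z_v <- if (mode == "anomaly") {
    pracma::trapz(grid, grid * area_g) / pracma::trapz(grid, area_g)
  } else {
    z_v_fixed
  }

  A_o <- hyps$area_m2[1]
  sc <- g / A_o * pracma::trapz(grid, rho_g * (grid - z_v) * area_g)

  out <- tibble::tibble(
    sc_J_m2 = sc,
    sc_kJ_m2 = sc / 1000,
    z_v_used = z_v,
    mode = mode,
    n_grid = length(grid),
    extrapolated = extrapolated)
  class(out) <- c("stability_result", class(out))
  out
}

#' Schmidt stability for a set of casts
#'
#' Convenience wrapper running [add_k20()], [density_profile()] and
#' [schmidt_stability()] over a list of CTD profiles.
#'
#' @param profiles A list of `ctd_profile` objects (raw conductivity or
#'   pre-computed k20).
#' @param hyps A `hypsometry` tibble.
#' @param params A [density_params()] object.
#' @param ... Passed on to [schmidt_stability()].
#' @return A tibble with one row per cast: `cast_id`, `date` and the
#'   stability columns.
#' @export
stability_series <- function(profiles, hyps, params = density_params(), ...) {
  purrr::map_dfr(profiles, function(p) {
    if (is.null(p[["k20_uScm"]])) p <- add_k20(p)
    res <- schmidt_stability(density_profile(p, params), hyps, ...)
    ts <- attr(p, "timestamp")
    dplyr::bind_cols(
      tibble::tibble(cast_id = attr(p, "cast_id"),
                     date = if (inherits(ts, c("Date", "POSIXct")))
                       as.Date(ts) else as.Date(NA)),
      res)
  })
}
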