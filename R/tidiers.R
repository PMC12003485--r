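# broom-style tidiers for fitted objects.

#' Tidy an interannual trend fit
#'
#' @param x An `annual_trend` object.
#' @param ... Passed to the underlying lm tidier machinery (unused).
#' @return A tibble with one row per model term (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy annual_trend
#' @export
tidy.annual_trend <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm),
                 estimate = unname(sm[, "Estimate"]),
                 std.error = unname(sm[, "Std. Error"]),
                 statistic = unname(sm[, "t value"]),
                 p.value = unname(sm[, "Pr(>|t|)"]))
}

#' Glance at an interannual trend fit
#'
#' @param x An `annual_trend` object.
#' @param ... Unused.
#' @return A one-row tibble with `slope_c_per_year`, `intercept_c`,
#'   `n_years`, `r.squared` and `sigma`.
#' @method glance annual_trend
#' @export
glance.annual_trend <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(slope_c_per_year = x$slope,
                 intercept_c = x$intercept,
                 n_years = x$n_years,
                 r.squared = sm$r.squared,
                 sigma = sm$sigma)
}

#' Tidy a Schmidt stability result
#'
#' @param x A `stability_result` one-row tibble.
#' @param ... Unused.
#' @return A long tibble with `quantity`, `value`, `unit`.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) {
  tibble::tibble(
    quantity = c("schmidt_stability", "schmidt_stability", "z_v"),
    value = c(x$sc_J_m2, x$sc_kJ_m2, x$z_v_used),
    unit = c("J m-2", "kJ m-2", "m"))
}

#' Glance at a Schmidt stability result
#'
#' @param x A `stability_result` one-row tibble.
#' @param ... Unused.
#' @return The one-row tibble, unclassed.
#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
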