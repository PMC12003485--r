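# ggplot2 helpers for profiles, layer seasons, phenotype counts and weather.

#' Plot a CTD profile's channels against depth
#'
#' Depth increases downward, the limnological convention.
#'
#' @param profile A `ctd_profile`.
#' @param channels Channel columns to draw (default: all present).
#' @return A ggplot object faceted by channel.
#' @export
plot_profile <- function(profile, channels = NULL) {
  chans <- channels %||% setdiff(names(profile), "depth_m")
  long <- tibble::as_tibble(profile) |>
    tidyr::pivot_longer(dplyr::all_of(chans),
                        names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$depth_m)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Depth (m)",
                  title = attr(profile, "cast_id"))
}

#' Plot a seasonal bacterial-layer series
#'
#' Layer extent as a ribbon between top and bottom with the 13.5 m horizon
#' drawn for reference.
#'
#' @param series Output of [bl_season_series()].
#' @param horizon_m Reference depth line (default 13.5 m).
#' @return A ggplot object.
#' @export
plot_bl_series <- function(series, horizon_m = 13.5) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$top_m,
                                      ymax = .data$bottom_m),
                         fill = "pink", alpha = 0.8) +
    ggplot2::geom_hline(yintercept = horizon_m, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "Depth (m)",
                  title = "Bacterial layer extent")
}

#' Plot phenotype concentrations by sampling position
#'
#' @param concentrations The `concentrations` tibble from
#'   [concentration_and_summary()].
#' @return A ggplot object.
#' @export
plot_phenotype_counts <- function(concentrations) {
  ggplot2::ggplot(concentrations,
                  ggplot2::aes(x = .data$sample_label,
                               y = .data$cells_per_ml,
                               fill = .data$phenotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(gsb = "darkgreen",
                                          small_psb = "grey60",
                                          large_psb = "purple")) +
    ggplot2::labs(x = "Position", y = "Cells per ml")
}

#' Plot monthly meteorological summaries
#'
#' @param monthly Output of [monthly_summary()].
#' @return A ggplot object with temperature, radiation and rainfall panels.
#' @export
plot_monthly_summary <- function(monthly) {
  long <- monthly |>
    dplyr::mutate(date = lubridate::make_date(.data$year, .data$month, 1)) |>
    tidyr::pivot_longer(dplyr::any_of(c("temp_mean_c", "net_radiation_J_m2",
                                        "rainfall_total_mm")),
                        names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
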