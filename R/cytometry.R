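# Flow-cytometry acquisition thresholds, phenotype gating and enumeration
# of anoxygenic phototrophic sulfur bacteria.

#' Flow-cytometry event table
#'
#' Events are a tibble with one row per particle and canonical channel
#' columns `fsc_h`, `fsc_a` (forward scatter height/area) and `fl1_a` ..
#' `fl4_a` (fluorescence areas); all values are non-negative instrument
#' units. The acquired volume and the sampling position travel as
#' attributes.
#'
#' @param events A data frame with at least `fsc_h`, `fsc_a`, `fl3_a`
#'   columns (common instrument spellings such as `FSC-H`, `FL3-A` are
#'   normalised automatically).
#' @param volume_ml Acquired volume in ml (> 0). Required for
#'   concentrations; instruments report it per run and it is not inferable
#'   from the events themselves.
#' @param sample_label Position label, one of `above_1m`, `bl_top`,
#'   `bl_mid_50cm`, `bl_bottom`, `below_1m` (or any other identifier).
#' @return A tibble of class `fcm_events`.
#' @export
fcm_events <- function(events, volume_ml, sample_label = "sample") {
  stopifnot(volume_ml > 0)
  out <- tibble::as_tibble(events)
  names(out) <- normalize_channel_names(names(out))
  num_cols <- vapply(out, is.numeric, logical(1))
  if (any(vapply(out[num_cols], function(v) any(v < 0, na.rm = TRUE),
                 logical(1)))) {
    rlang::abort("Channel values must be non-negative.",
                 class = "meromix_error_domain")
  }
  attr(out, "volume_ml") <- volume_ml
  attr(out, "sample_label") <- sample_label
  class(out) <- c("fcm_events", class(tibble::tibble()))
  out
}

normalize_channel_names <- function(nms) {
  canon <- gsub("[^a-z0-9]+", "_", tolower(nms))
  canon <- sub("_$", "", canon)
  canon
}

#' Read a delimited flow-cytometry event export
#'
#' Reads comma- or tab-delimited text with one row per event and named
#' channel columns (`FSC-H`, `FSC-A`, `FL1-A` .. `FL4-A` in any common
#' spelling).
#'
#' @param path File path.
#' @inheritParams fcm_events
#' @return A `fcm_events` tibble.
#' @export
read_fcm_table <- function(path, volume_ml, sample_label = "sample") {
  fcm_events(read_delim_table(path), volume_ml = volume_ml,
             sample_label = sample_label)
}

#' Gating configuration
#'
#' @param fsch_threshold Acquisition threshold on forward-scatter height;
#'   events at or below it are discarded as abiotic particles (default
#'   2000).
#' @param fl3a_threshold Red-fluorescence threshold on FL3-A separating
#'   (bacterio)chlorophyll autofluorescent cells from the rest (default
#'   1100). Both thresholds are strict (`>`).
#' @param size_cuts Two increasing cuts on log10(FSC-A) separating the
#'   three phenotypes by cell size: below the first cut green sulfur
#'   bacteria (GSB, < 1 um cells), between the cuts small-celled purple
#'   sulfur bacteria (~4 um), above the second large-celled PSB (~10 um).
#'   Defaults 4.5 and 5.5.
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(fsch_threshold = 2000, fl3a_threshold = 1100,
                          size_cuts = c(4.5, 5.5)) {
  stopifnot(fsch_threshold >= 0, fl3a_threshold >= 0,
            length(size_cuts) == 2, diff(size_cuts) > 0)
  structure(list(fsch_threshold = fsch_threshold,
                 fl3a_threshold = fl3a_threshold,
                 size_cuts = size_cuts),
            class = "gating_config")
}

#' Apply the acquisition thresholds
#'
#' Retains events with `fsc_h` strictly above the scatter threshold (the
#' instrument's abiotic-particle exclusion) and `fl3_a` strictly above the
#' red-fluorescence threshold (autofluorescent phototrophs only). The
#' acquired volume is unchanged: thresholding discards particles, not
#' sample.
#'
#' @param events A `fcm_events` tibble.
#' @param config A [gating_config()].
#' @return The filtered `fcm_events` tibble.
#' @export
apply_acquisition_thresholds <- function(events, config = gating_config()) {
  for (ch in c("fsc_h", "fl3_a")) {
    if (is.null(events[[ch]])) {
      rlang::abort(sprintf("Events lack required channel '%s'.", ch),
                   class = "meromix_error_missing_channel")
    }
  }
  keep <- events$fsc_h > config$fsch_threshold &
    events$fl3_a > config$fl3a_threshold
  out <- events[keep, , drop = FALSE]
  attr(out, "volume_ml") <- attr(events, "volume_ml")
  attr(out, "sample_label") <- attr(events, "sample_label")
  class(out) <- class(events)
  out
}

#' Classify retained events into the three phototroph phenotypes
#'
#' One-dimensional size gating on log10(FSC-A): `gsb` below the first cut,
#' `small_psb` in the left-closed interval between the cuts, `large_psb` at
#' and above the second cut. The rule is deterministic and independent of
#' event order. Events with zero forward-scatter area (unclassifiable on a
#' log scale) are labelled `NA`, excluded from counts and tallied in the
#' `n_unclassifiable` attribute.
#'
#' @param events A thresholded `fcm_events` tibble (see
#'   [apply_acquisition_thresholds()]).
#' @param config A [gating_config()].
#' @return The events tibble with a `phenotype` factor column
#'   (`gsb`, `small_psb`, `large_psb`).
#' @export
classify_phenotypes <- function(events, config = gating_config()) {
  if (is.null(events[["fsc_a"]])) {
    rlang::abort("Events lack required channel 'fsc_a'.",
                 class = "meromix_error_missing_channel")
  }
  cuts <- config$size_cuts
  lg <- ifelse(events[["fsc_a"]] > 0, log10(pmax(events[["fsc_a"]], .Machine$double.xmin)),
               NA_real_)
  lab <- dplyr::case_when(
    is.na(lg) ~ NA_character_,
    lg < cuts[1] ~ "gsb",
    lg < cuts[2] ~ "small_psb",
    TRUE ~ "large_psb")
  out <- events
  out$phenotype <- factor(lab, levels = c("gsb", "small_psb", "large_psb"))
  n_bad <- sum(is.na(lab))
  if (n_bad > 0) {
    rlang::inform(sprintf("%d event(s) with FSC-A = 0 left unclassified.",
                          n_bad))
  }
  attr(out, "n_unclassifiable") <- n_bad
  attr(out, "volume_ml") <- attr(events, "volume_ml")
  attr(out, "sample_label") <- attr(events, "sample_label")
  class(out) <- class(events)
  out
}

#' Concentrations per sample and bacterial-layer summary statistics
#'
#' For each labelled event table, per-phenotype concentration is
#' `count / acquired volume` (cells per ml). The layer-level summary per
#' phenotype is the arithmetic mean and sample standard deviation (n - 1
#' denominator) of the concentrations at the three in-layer positions
#' (`bl_top`, `bl_mid_50cm`, `bl_bottom`); the above/below flanking
#' positions are reported in the concentration table but excluded from the
#' layer mean. With fewer than two in-layer positions the sd is `NA` and
#' the mean is taken over whatever is available.
#'
#' @param tables A list of classified `fcm_events` tibbles (each carrying
#'   `sample_label` and `volume_ml` attributes), or a single such table.
#' @return A list with `concentrations` (tibble: `sample_label`,
#'   `phenotype`, `count`, `volume_ml`, `cells_per_ml`) and `bl_summary`
#'   (tibble: `phenotype`, `n_positions`, `mean_cells_per_ml`,
#'   `sd_cells_per_ml`).
#' @export
concentration_and_summary <- function(tables) {
  if (inherits(tables, "fcm_events")) tables <- list(tables)
  conc <- purrr::map_dfr(tables, function(tb) {
    if (is.null(tb[["phenotype"]])) {
      rlang::abort("Events must be classified first (classify_phenotypes).",
                   class = "meromix_error_schema")
    }
    vol <- attr(tb, "volume_ml")
    counts <- table(tb[["phenotype"]])  # drops NA-labelled events
    tibble::tibble(
      sample_label = attr(tb, "sample_label") %||% "sample",
      phenotype = names(counts),
      count = as.integer(counts),
      volume_ml = vol,
      cells_per_ml = as.integer(counts) / vol)
  })
  bl_positions <- c("bl_top", "bl_mid_50cm", "bl_bottom")
  bl <- conc |>
    dplyr::filter(.data$sample_label %in% bl_positions) |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(
      n_positions = dplyr::n(),
      mean_cells_per_ml = mean(.data$cells_per_ml),
      sd_cells_per_ml = ifelse(dplyr::n() >= 2,
                               stats::sd(.data$cells_per_ml), NA_real_),
      .groups = "drop")
  list(concentrations = conc, bl_summary = bl)
}
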