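test_that("acquisition thresholds are strict on both channels", {
  ev <- fcm_events(data.frame(
    fsc_h = c(1500, 50000, 2001, 2000, 3000),
    fsc_a = c(2000, 60000, 2500, 2500, 3500),
    fl3_a = c(5000, 1000, 1101, 1101, 1100)),
    volume_ml = 0.05)
  kept <- apply_acquisition_thresholds(ev)
  # only (2001, 1101) passes both strict comparisons
  expect_equal(nrow(kept), 1)
  expect_equal(kept$fsc_h, 2001)
  expect_equal(attr(kept, "volume_ml"), 0.05)

  # idempotent
  expect_equal(nrow(apply_acquisition_thresholds(kept)), 1)

  noch <- tibble::as_tibble(ev)[, "fsc_h", drop = FALSE]
  attr(noch, "volume_ml") <- 0.05
  class(noch) <- class(ev)
  expect_error(apply_acquisition_thresholds(noch),
               class = "meromix_error_missing_channel")
})

test_that("size gating partitions well-separated clusters almost perfectly", {
  ev <- exact_clusters(n_each = 1000)
  cl <- classify_phenotypes(apply_acquisition_thresholds(ev))
  counts <- table(cl$phenotype)
  expect_lte(abs(counts[["gsb"]] - 1000), 1)
  expect_lte(abs(counts[["small_psb"]] - 1000), 1)
  expect_lte(abs(counts[["large_psb"]] - 1000), 1)
  # per-event check against truth: 5-sigma separation, at most 1 crossing
  expect_lte(sum(as.character(cl$phenotype) != cl$phenotype_true), 1)
  # classification is a partition of the retained classifiable events
  expect_false(any(is.na(cl$phenotype)))
})

test_that("size-cut boundaries use the left-closed interval convention", {
  ev <- fcm_events(data.frame(fsc_h = rep(1e5, 3),
                              fsc_a = 10^c(4.5, 5.5, 4.499),
                              fl3_a = rep(1e4, 3)), volume_ml = 0.05)
  cl <- classify_phenotypes(ev)
  expect_equal(as.character(cl$phenotype),
               c("small_psb", "large_psb", "gsb"))

  empty <- fcm_events(data.frame(fsc_h = double(), fsc_a = double(),
                                 fl3_a = double()), volume_ml = 0.05)
  expect_equal(nrow(classify_phenotypes(empty)), 0)

  zero <- fcm_events(data.frame(fsc_h = c(3000, 3000),
                                fsc_a = c(0, 1e5),
                                fl3_a = c(2000, 2000)), volume_ml = 0.05)
  expect_message(cl0 <- classify_phenotypes(zero), "unclassified")
  expect_true(is.na(cl0$phenotype[1]))
  expect_equal(attr(cl0, "n_unclassifiable"), 1)
})

test_that("concentrations and layer summaries follow count/volume arithmetic", {
  mk <- function(label, n_by_pheno, vol = 0.05) {
    lg <- unlist(purrr::imap(n_by_pheno, function(n, ph) {
      rep(c(gsb = 4, small_psb = 5, large_psb = 6)[[ph]], n)
    }))
    classify_phenotypes(fcm_events(
      data.frame(fsc_h = rep(1e5, length(lg)), fsc_a = 10^lg,
                 fl3_a = rep(1e4, length(lg))),
      volume_ml = vol, sample_label = label))
  }
  # 5000 events in 0.05 ml -> 1e5 cells/ml
  res1 <- concentration_and_summary(mk("bl_top", c(gsb = 5000)))
  conc1 <- dplyr::filter(res1$concentrations, .data$phenotype == "gsb")
  expect_equal(conc1$cells_per_ml, 1e5)

  # layer mean/sd over the three in-layer positions; flanks excluded
  tables <- list(mk("bl_top", c(gsb = 5000)),
                 mk("bl_mid_50cm", c(gsb = 10000)),
                 mk("bl_bottom", c(gsb = 15000)),
                 mk("above_1m", c(gsb = 100000)))
  res <- concentration_and_summary(tables)
  g <- dplyr::filter(res$bl_summary, .data$phenotype == "gsb")
  expect_equal(g$n_positions, 3)
  expect_equal(g$mean_cells_per_ml, 2e5)
  expect_equal(g$sd_cells_per_ml, 1e5)

  # identical concentrations -> sd 0; single position -> sd NA
  same <- concentration_and_summary(list(mk("bl_top", c(gsb = 5000)),
                                         mk("bl_mid_50cm", c(gsb = 5000)),
                                         mk("bl_bottom", c(gsb = 5000))))
  expect_equal(dplyr::filter(same$bl_summary,
                             .data$phenotype == "gsb")$sd_cells_per_ml, 0)
  solo <- concentration_and_summary(mk("bl_top", c(gsb = 5000)))
  expect_true(is.na(dplyr::filter(solo$bl_summary,
                                  .data$phenotype == "gsb")$sd_cells_per_ml))
})

test_that("concentration scales linearly with count and inversely with volume", {
  base <- exact_clusters(n_each = 500, volume_ml = 0.05,
                         sample_label = "bl_top")
  cl <- classify_phenotypes(base)
  c1 <- concentration_and_summary(cl)$concentrations
  half_vol <- cl
  attr(half_vol, "volume_ml") <- 0.025
  c2 <- concentration_and_summary(half_vol)$concentrations
  expect_equal(c2$cells_per_ml, 2 * c1$cells_per_ml)
  expect_equal(c1$cells_per_ml, c1$count / 0.05)
})

test_that("phenotype fractions are recovered within 2% on seeded mixtures", {
  fr <- c(gsb = 0.2, small_psb = 0.5, large_psb = 0.3)
  ev <- gen_fcm_events(fractions = fr, n = 10000, seed = 11)
  cl <- classify_phenotypes(apply_acquisition_thresholds(ev))
  got <- as.numeric(table(cl$phenotype)) / nrow(cl)
  expect_true(all(abs(got - fr) < 0.02))
})
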