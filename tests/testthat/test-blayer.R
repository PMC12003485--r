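gaussian_turb_profile <- function(center = 13, sigma = 0.5, peak = 24,
                                  baseline = 1, step = 0.1) {
  z <- seq(0, 21, by = step)
  ctd_profile(depth_m = z, temp_c = rep(5, length(z)),
              turb_ftu = baseline + peak * exp(-(z - center)^2 /
                                                 (2 * sigma^2)))
}

test_that("bacterial layer detection recovers analytic threshold crossings", {
  # all sub-threshold: nothing detected
  z <- seq(0, 21, 0.1)
  flat <- ctd_profile(depth_m = z, temp_c = rep(5, length(z)),
                      turb_ftu = rep(1, length(z)))
  expect_null(detect_bacterial_layer(flat))

  # Gaussian peak: crossings at 13 +/- sqrt(2 sigma^2 ln(24/9)) = 13 +/- 0.700
  p <- gaussian_turb_profile()
  bl <- detect_bacterial_layer(p, threshold = 10)
  half <- sqrt(2 * 0.5^2 * log(24 / 9))
  expect_equal(bl$top_m, 13 - half, tolerance = 0.1)
  expect_equal(bl$bottom_m, 13 + half, tolerance = 0.1)
  expect_equal(bl$thickness_m, 1.40, tolerance = 0.02)
  expect_equal(bl$peak_depth_m, 13.0)
  expect_equal(bl$thickness_m, bl$bottom_m - bl$top_m)
  expect_gt(bl$peak_turb_ftu, bl$threshold_ftu)

  # missing channel is a typed error
  bare <- ctd_profile(depth_m = z, temp_c = rep(5, length(z)))
  expect_error(detect_bacterial_layer(bare),
               class = "meromix_error_missing_channel")
})

test_that("among multiple super-threshold intervals the global maximum wins", {
  z <- seq(0, 21, 0.1)
  turb <- 1 + 14 * exp(-(z - 8)^2 / (2 * 0.4^2)) +
    24 * exp(-(z - 13)^2 / (2 * 0.4^2))
  p <- ctd_profile(depth_m = z, temp_c = rep(5, length(z)), turb_ftu = turb)
  bl <- detect_bacterial_layer(p, threshold = 10)
  expect_equal(bl$peak_depth_m, 13.0)
  bl_deep <- detect_bacterial_layer(p, threshold = 10, select = "deepest")
  expect_equal(bl_deep$peak_depth_m, 13.0)
  # detection is insensitive to sub-threshold baseline noise away from the peak
  turb2 <- turb + ifelse(abs(z - 13) > 2 & abs(z - 8) > 2, 3, 0)
  p2 <- ctd_profile(depth_m = z, temp_c = rep(5, length(z)), turb_ftu = turb2)
  expect_equal(detect_bacterial_layer(p2, threshold = 10)$top_m, bl$top_m)
})

test_that("sampling plan applies the five-depth rule with boundary clipping", {
  bl <- tibble::tibble(top_m = 12.3, bottom_m = 13.7)
  plan <- plan_sampling_depths(bl, z_bot = 21)
  expect_equal(plan$depth_m, c(11.3, 12.3, 12.8, 13.7, 14.7))
  expect_equal(plan$label, c("above_1m", "bl_top", "bl_mid_50cm",
                             "bl_bottom", "below_1m"))
  expect_false(any(plan$clipped))
  expect_true(all(diff(plan$depth_m) > 0))

  shallow <- plan_sampling_depths(tibble::tibble(top_m = 0.5, bottom_m = 1.0))
  expect_equal(shallow$depth_m[1], 0)
  expect_true(shallow$clipped[1])

  deep <- plan_sampling_depths(tibble::tibble(top_m = 12, bottom_m = 19.5),
                               z_bot = 20)
  expect_equal(deep$depth_m[5], 20)
  expect_true(deep$clipped[5])
})

test_that("isotherm depth interpolates the shallowest crossing", {
  z <- seq(0, 20, 0.5)
  p <- ctd_profile(depth_m = z, temp_c = 15 - 0.5 * z)
  expect_equal(isotherm_depth(p, 10), 10.0)

  cold <- ctd_profile(depth_m = c(0, 5, 10), temp_c = c(4, 4, 4))
  expect_true(is.na(isotherm_depth(cold, 10)))

  p2 <- ctd_profile(depth_m = c(0, 9, 11, 20), temp_c = c(15, 11, 9, 5))
  expect_equal(isotherm_depth(p2, 10), 10.0)
})

test_that("oxycline depth finds the first drop below the threshold", {
  z <- c(0, 5, 10)
  oxic <- ctd_profile(depth_m = z, temp_c = rep(10, 3),
                      do_mgL = rep(8, 3))
  expect_true(is.na(oxycline_depth(oxic)))

  p <- ctd_profile(depth_m = c(0, 9, 10, 12), temp_c = rep(10, 4),
                   do_mgL = c(8, 8, 0.4, 0))
  expect_equal(oxycline_depth(p, 0.5), 9 + (8 - 0.5) / (8 - 0.4),
               tolerance = 1e-6)

  # sigmoidal decay from the generator: analytic crossing of the logistic
  sc <- lake_scenario()
  prof <- gen_ctd_profile(sc)
  expected <- sc$do_cline_depth -
    sc$do_cline_width * stats::qlogis(0.5 / sc$do_surface)
  expect_equal(oxycline_depth(prof, 0.5), expected, tolerance = 0.05)
  expect_true(oxycline_depth(prof, 0.5) > 10 &&
                oxycline_depth(prof, 0.5) < 12)
})

test_that("seasonal series records layer geometry and gaps chronologically", {
  p1 <- gaussian_turb_profile()
  attr(p1, "timestamp") <- as.POSIXct("2020-07-01", tz = "UTC")
  z <- seq(0, 21, 0.1)
  no_bl <- ctd_profile(depth_m = z, temp_c = rep(5, length(z)),
                       turb_ftu = rep(1, length(z)), cast_id = "empty")
  attr(no_bl, "timestamp") <- as.POSIXct("2020-06-01", tz = "UTC")

  series <- bl_season_series(list(p1, no_bl))
  expect_equal(nrow(series), 2)
  expect_equal(series$date, as.Date(c("2020-06-01", "2020-07-01")))
  expect_true(is.na(series$top_m[1]))            # gap row for the empty cast
  expect_false(series$above_13_5[2])             # bottom 13.7 >= 13.5

  shallow <- gaussian_turb_profile(center = 12, sigma = 0.3)
  attr(shallow, "timestamp") <- as.POSIXct("2020-08-01", tz = "UTC")
  s2 <- bl_season_series(list(shallow))
  expect_true(s2$above_13_5[1])

  expect_equal(nrow(bl_season_series(list())), 0)
})

test_that("detection closes the loop with the synthetic generator", {
  season <- gen_season(season_scenario(n_casts = 6))
  series <- bl_season_series(season$profiles)
  truth <- season$truth
  expect_equal(series$top_m, truth$top_m, tolerance = 0.1)
  expect_equal(series$bottom_m, truth$bottom_m, tolerance = 0.1)
  # constant-width trajectory: detected thickness varies by < 2 grid steps
  flat <- gen_season(season_scenario(n_casts = 5, bl_sigma_start = 0.5,
                                     bl_sigma_end = 0.5))
  th <- bl_season_series(flat$profiles)$thickness_m
  expect_lt(stats::sd(th), 0.2)
})
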