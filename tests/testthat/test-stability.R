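test_that("water density reproduces the cubic equation of state", {
  expect_equal(water_density(0, 0), 999.84)
  expect_equal(water_density(4, 0), 999.9688, tolerance = 1e-6)
  expect_equal(water_density(15, 0), 999.0970, tolerance = 1e-6)
  expect_error(water_density(45), class = "meromix_error_domain")
})

test_that("density maximum sits near 3.99 degrees C (brute-force scan)", {
  ts <- seq(0, 8, by = 0.001)
  rho <- water_density(ts, 0)
  t_max <- ts[which.max(rho)]
  expect_equal(t_max, 3.99, tolerance = 0.01)
  expect_gt(water_density(3.99, 0), water_density(0, 0))
  expect_gt(water_density(3.99, 0), water_density(8, 0))
})

test_that("salinity term follows S = alpha_s * k20 with dimensionless beta", {
  expect_equal(salinity_from_k20(0), 0)
  expect_equal(salinity_from_k20(400), 0.288)
  expect_equal(salinity_from_k20(200), 0.144)
  expect_error(salinity_from_k20(-1), class = "meromix_error_domain")
  # density contribution at k20 = 400: beta * alpha_s * 400
  expect_equal(water_density(10, 400) - water_density(10, 0), 0.27648,
               tolerance = 1e-9)
  # literal published reading available through config
  lit <- density_params(beta = 0.96e-3)
  # the subtraction of ~1000 kg m-3 values limits precision to ~1e-13 abs
  expect_equal(water_density(10, 400, lit) - water_density(10, 0, lit),
               0.96e-3 * 0.288, tolerance = 1e-4)
})

test_that("parametric hypsometry and centre of volume match closed forms", {
  box <- parametric_hypsometry(A_o = 5e5, z_bot = 21, q = 0)
  expect_true(all(box$area_m2 == 5e5))
  expect_equal(center_of_volume(box), 10.5, tolerance = 1e-6)

  cone <- parametric_hypsometry(A_o = 1e6, z_bot = 21, q = 1)
  expect_equal(stats::approx(cone$depth_m, cone$area_m2, 10.5)$y, 5e5)

  # closed form z_v = z_bot / (q + 2) for the power-law family
  for (q in c(1, 1.96, 2, 3)) {
    h <- parametric_hypsometry(A_o = 0.23e6, z_bot = 21, q = q, n = 2101)
    expect_equal(center_of_volume(h), 21 / (q + 2), tolerance = 1e-3)
  }
  # the published basin: q = 1.96 gives the printed 5.3 m
  h <- parametric_hypsometry(A_o = 0.23e6, z_bot = 21, q = 1.96)
  expect_equal(center_of_volume(h), 5.30, tolerance = 0.01)
})

test_that("Schmidt stability reproduces the analytic oracles", {
  box <- box_lake()
  # uniform density: zero work in anomaly mode
  z <- seq(0, 21, 0.1)
  uni <- tibble::tibble(depth_m = z, density_kg_m3 = rep(1000, length(z)))
  expect_lt(abs(schmidt_stability(uni, box, mode = "anomaly")$sc_J_m2), 1e-6)

  # two-layer: Sc = g * drho * h1 * h2 / 2 for a box lake
  sc2 <- schmidt_stability(two_layer_density(), box, mode = "anomaly")
  expect_equal(sc2$sc_J_m2, 9.81 * 1.2 * 10 * 11 / 2, tolerance = 1e-3)
  expect_equal(sc2$sc_kJ_m2, sc2$sc_J_m2 / 1000)

  # linear gradient: Sc = g * gamma * H^3 / 12
  sc3 <- schmidt_stability(linear_density(), box, mode = "anomaly")
  expect_equal(sc3$sc_J_m2, 9.81 * 0.1 * 21^3 / 12, tolerance = 1e-3)
})

test_that("trapezoidal Sc converges at second order on the linear oracle", {
  box <- parametric_hypsometry(A_o = 1e6, z_bot = 21, q = 0, n = 2101)
  exact <- 9.81 * 0.1 * 21^3 / 12
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    abs(schmidt_stability(linear_density(step = h), box, mode = "anomaly",
                          grid_step = h)$sc_J_m2 - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_gt(err[2] / err[3], 3)
})

test_that("as_printed mode matches anomaly mode when z_v coincides", {
  hyp <- parametric_hypsometry(A_o = 0.23e6, z_bot = 21, q = 1.96)
  dp <- two_layer_density()
  an <- schmidt_stability(dp, hyp, mode = "anomaly")
  ap <- schmidt_stability(dp, hyp, mode = "as_printed",
                          z_v_fixed = an$z_v_used)
  expect_equal(ap$sc_J_m2, an$sc_J_m2, tolerance = 1e-9)
  expect_error(schmidt_stability(dp, hyp, z_v_fixed = 30),
               class = "meromix_error_domain")
})

test_that("anomaly-mode Sc is offset-invariant, monotone in drho and
           independent of overall area scale", {
  box <- box_lake()
  dp <- two_layer_density()
  base <- schmidt_stability(dp, box, mode = "anomaly")$sc_J_m2
  for (c0 in c(-5, 2, 100)) {
    shifted <- dplyr::mutate(dp, density_kg_m3 = density_kg_m3 + c0)
    expect_equal(schmidt_stability(shifted, box, mode = "anomaly")$sc_J_m2,
                 base, tolerance = 1e-8)
  }
  scs <- vapply(c(0.3, 0.6, 1.2, 2.4), function(dr) {
    schmidt_stability(two_layer_density(delta_rho = dr), box,
                      mode = "anomaly")$sc_J_m2
  }, numeric(1))
  expect_true(all(diff(scs) > 0))

  doubled <- box
  doubled$area_m2 <- 2 * doubled$area_m2
  expect_equal(schmidt_stability(dp, doubled, mode = "anomaly")$sc_J_m2,
               base, tolerance = 1e-10)
})

test_that("stability_series runs the full per-cast chain", {
  season <- gen_season(season_scenario(n_casts = 3))
  hyp <- parametric_hypsometry()
  res <- stability_series(season$profiles, hyp)
  expect_equal(nrow(res), 3)
  expect_true(all(res$sc_J_m2 > 0))
  expect_equal(res$mode, rep("as_printed", 3))
  # tidier surface
  expect_s3_class(tidy(schmidt_stability(two_layer_density(), hyp)),
                  "tbl_df")
})
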