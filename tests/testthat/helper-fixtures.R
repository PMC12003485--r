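# Shared fixture builders; everything is generated in code.

simple_ctd_df <- function() {
  data.frame(Depth = c(1, 2, 3), Temp = c(15, 10, 5), Cond = c(150, 200, 250))
}

simple_map <- c(depth = "Depth", temperature = "Temp", conductivity = "Cond")

# box-lake hypsometry and simple density profiles on a fixed grid
box_lake <- function(z_bot = 21, n = 211) {
  parametric_hypsometry(A_o = 1e6, z_bot = z_bot, q = 0, n = n)
}

two_layer_density <- function(delta_rho = 1.2, interface = 10, z_bot = 21,
                              step = 0.1, rho0 = 1000) {
  z <- seq(0, z_bot, by = step)
  tibble::tibble(depth_m = z,
                 density_kg_m3 = rho0 + ifelse(z > interface, delta_rho, 0))
}

linear_density <- function(gamma = 0.1, z_bot = 21, step = 0.1, rho0 = 1000) {
  z <- seq(0, z_bot, by = step)
  tibble::tibble(depth_m = z, density_kg_m3 = rho0 + gamma * z)
}

# event table with exactly n_each events per phenotype cluster
exact_clusters <- function(n_each = 1000, means = c(4, 5, 6), sd = 0.1,
                           seed = 42, volume_ml = 0.05,
                           sample_label = "sample") {
  withr::with_seed(seed, {
    lg <- c(rnorm(n_each, means[1], sd), rnorm(n_each, means[2], sd),
            rnorm(n_each, means[3], sd))
  })
  fsc_a <- 10^lg
  fcm_events(
    data.frame(fsc_h = 0.8 * fsc_a, fsc_a = fsc_a,
               fl3_a = 10^4,
               phenotype_true = rep(c("gsb", "small_psb", "large_psb"),
                                    each = n_each)),
    volume_ml = volume_ml, sample_label = sample_label)
}
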