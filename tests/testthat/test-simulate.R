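test_that("trap counts are Poisson around the latent density", {
  # sd = 0 collapses the log-normal, so every station has lambda = 4
  cfg <- design_config(n_locations = 2500, replicates_per_distance = 1,
                       n_e3_stations = 0, treatments = "control")
  d <- generate_design(cfg, seed = 1)
  p <- community_params(n_species = 1, total_seed_density = 4,
                        seed_density_lognormal_sd = 0, rng_seed = 5)
  rain <- simulate_seed_rain(d, p)
  expect_true(all(rain$truth$lambda == 4))
  n_traps <- nrow(d$traps)
  mean_count <- sum(rain$traps$count) / n_traps  # zeros are implicit
  se <- sqrt(4 / n_traps)
  expect_lt(abs(mean_count - 4), 3 * se)
  # trap-pair mean tracks lambda when lambda varies among stations
  p2 <- community_params(n_species = 1, total_seed_density = 10,
                         seed_density_lognormal_sd = 0.8, rng_seed = 6)
  rain2 <- simulate_seed_rain(d, p2)
  pair_mean <- sum(rain2$traps$count) / 2 / nrow(d$stations)
  lam_mean <- mean(rain2$truth$lambda)
  se2 <- sqrt(sum(rain2$truth$lambda) / 2) / nrow(d$stations)
  expect_lt(abs(pair_mean - lam_mean), 3 * se2)
})

test_that("zero latent density yields zero seeds and zero recruits", {
  sim <- tiny_dataset()
  d <- generate_design(design_config(n_locations = 3,
                                     replicates_per_distance = 1,
                                     n_e3_stations = 3, n_e3_locations = 3),
                       seed = 42)
  truth <- sim$truth
  truth$lambda[, "SP001"] <- 0
  sl <- simulate_recruitment(truth, d)
  expect_false("SP001" %in% sl$species_id)
})

test_that("recruitment follows the power-law mean", {
  # a = 0.2, b = 1, lambda = 50 -> 10 expected recruits per plot;
  # near-Poisson dispersion makes the Monte-Carlo check tight
  cfg <- design_config(n_locations = 2000, replicates_per_distance = 1,
                       n_e3_stations = 0, treatments = "control")
  d <- generate_design(cfg, seed = 2)
  bmat <- matrix(1, 3, 1, dimnames = list(c("E0", "E1", "E2"), "Control"))
  p <- community_params(n_species = 1, total_seed_density = 50,
                        seed_density_lognormal_sd = 0, a_mean = 0.2,
                        a_logit_sd = 0, b_matrix = bmat,
                        species_slope_sd = 0, nb_dispersion = 1e6,
                        rng_seed = 3)
  rain <- simulate_seed_rain(d, p)
  sl <- simulate_recruitment(rain$truth, d)
  n_plots <- nrow(d$plots)
  m <- sum(sl$recruits) / n_plots
  expect_lt(abs(m - 10), 3 * sqrt(10 / n_plots))
  # NB -> Poisson limit: variance approaches the mean for large size phi
  per_plot <- rep(0, n_plots)
  agg <- tapply(sl$recruits, sl$plot_id, sum)
  per_plot[match(names(agg), d$plots$plot_id)] <- agg
  expect_lt(abs(stats::var(per_plot) / mean(per_plot) - 1), 0.1)
})

test_that("b = 1 gives a unit log-log slope across stations", {
  cfg <- design_config(n_locations = 150, replicates_per_distance = 1,
                       n_e3_stations = 0, treatments = "control")
  d <- generate_design(cfg, seed = 4)
  bmat <- matrix(1, 3, 1, dimnames = list(c("E0", "E1", "E2"), "Control"))
  p <- community_params(n_species = 1, total_seed_density = 40,
                        seed_density_lognormal_sd = 1, a_mean = 0.3,
                        a_logit_sd = 0, b_matrix = bmat, species_slope_sd = 0,
                        nb_dispersion = 1e5, rng_seed = 8)
  rain <- simulate_seed_rain(d, p)
  sl <- simulate_recruitment(rain$truth, d)
  lam <- rain$truth$lambda[, 1]
  rec <- rep(0, length(lam))
  agg <- tapply(sl$recruits, sl$station_id, sum)
  rec[match(names(agg), names(lam))] <- agg
  keep <- rec > 0
  slope <- stats::coef(stats::lm(log(rec[keep]) ~ log(lam[keep])))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  s1 <- tiny_dataset(seed = 99)
  s2 <- tiny_dataset(seed = 99)
  expect_identical(s1$data$traps, s2$data$traps)
  expect_identical(s1$data$seedlings, s2$data$seedlings)
  expect_identical(s1$truth$lambda, s2$truth$lambda)
  s3 <- tiny_dataset(seed = 100)
  expect_false(identical(s1$data$traps, s3$data$traps))
})

test_that("log-series abundance draws are valid probabilities", {
  p <- community_params(n_species = 200, rng_seed = 1)
  w <- edgecndd:::draw_relative_abundance(p)
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
  # log-series communities are dominance-skewed
  expect_gt(max(w) / min(w), 10)
})
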