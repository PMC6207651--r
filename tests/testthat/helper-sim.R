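# shared builders for scaled-down simulation studies

# single-cell community on a 3-band edge design (no E3), control plots only
recovery_params <- function(seed, beta = 0.7, n_species = 20,
                            total_seed_density = 600,
                            edges = c("E0", "E1", "E2")) {
  community_params(
    n_species = n_species,
    abundance = list(model = "lognormal", sdlog = 1),
    total_seed_density = total_seed_density,
    b_matrix = matrix(beta, length(edges), 1,
                      dimnames = list(edges, "Control")),
    rng_seed = seed)
}

recovery_design <- function(n_stations, treatments = "control") {
  stopifnot(n_stations %% 3 == 0)
  design_config(n_locations = n_stations / 3, replicates_per_distance = 1,
                n_e3_stations = 0, treatments = treatments)
}

# simulate, filter, and fit one single-slope dataset; returns summary row
fit_single_slope <- function(seed, beta, n_stations, n_species,
                             total_seed_density = 600,
                             iter = 700, warmup = 250, naive = FALSE,
                             treatments = "control") {
  p <- recovery_params(seed, beta = beta, n_species = n_species,
                       total_seed_density = total_seed_density)
  sim <- simulate_dataset(recovery_design(n_stations, treatments), p)
  flt <- filter_species(sim$data)
  spec <- cndd_model_spec(chains = 1, iter = iter, warmup = warmup,
                          seed = seed, cells = "single")
  f <- if (naive) fit_naive_model else fit_cndd_model
  fit <- suppressWarnings(f(sim$data, flt$species, spec))
  fit$summary
}

# deterministic small dataset for io / filter tests
tiny_dataset <- function(seed = 42) {
  p <- community_params(n_species = 10,
                        abundance = list(model = "lognormal", sdlog = 1),
                        total_seed_density = 120, rng_seed = seed)
  cfg <- design_config(n_locations = 3, replicates_per_distance = 1,
                       n_e3_stations = 3, n_e3_locations = 3)
  simulate_dataset(cfg, p)
}

# abundance vector of one seedling plot
plot_counts <- function(data, plot_id) {
  x <- data$seedlings[data$seedlings$plot_id == plot_id, ]
  tapply(x$recruits, x$species_id, sum)
}

# Monte-Carlo rarefaction oracle: mean distinct species over resamples
mc_rarefy <- function(counts, n, reps = 10000) {
  pool <- rep(seq_along(counts), counts)
  draws <- vapply(seq_len(reps), function(i) {
    length(unique(sample(pool, n)))
  }, numeric(1))
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}
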