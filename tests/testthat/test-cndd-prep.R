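# hand-built dataset with controlled occupancy for the species filter
filter_fixture <- function() {
  n <- 12
  stations <- data.frame(station_id = sprintf("S%02d", 1:n),
                         location_id = "L01", edge_category = "E0",
                         stringsAsFactors = FALSE)
  plots <- data.frame(plot_id = paste0(stations$station_id, "_P1"),
                      station_id = stations$station_id,
                      treatment = "control", stringsAsFactors = FALSE)
  # A: 12 stations, density 1..10 per trap-pair mean, 8 seedlings -> retained
  trapsA <- data.frame(station_id = stations$station_id, trap_id = 1,
                       species_id = "A", count = c(2, 2:10, 20, 20))
  # B: wide occupancy and density but only 4 seedlings -> excluded
  trapsB <- data.frame(station_id = stations$station_id, trap_id = 1,
                       species_id = "B", count = c(2, 2:10, 20, 20))
  # C: only 9 stations -> excluded
  trapsC <- data.frame(station_id = stations$station_id[1:9], trap_id = 1,
                       species_id = "C", count = c(1, 1, 2, 2, 4, 4, 9, 9, 9))
  # D: abundant everywhere but flat density (fold 2 < 3) -> excluded
  trapsD <- data.frame(station_id = stations$station_id, trap_id = 1,
                       species_id = "D", count = c(rep(4, 6), rep(8, 6)))
  seedlings <- rbind(
    data.frame(plot_id = plots$plot_id[1:8], species_id = "A", recruits = 1),
    data.frame(plot_id = plots$plot_id[1:4], species_id = "B", recruits = 1),
    data.frame(plot_id = plots$plot_id[1:9], species_id = "C", recruits = 1),
    data.frame(plot_id = plots$plot_id[1:6], species_id = "D", recruits = 1))
  edge_data(stations, plots, rbind(trapsA, trapsB, trapsC, trapsD),
            seedlings)
}

test_that("the species filter applies all three inclusion rules", {
  flt <- filter_species(filter_fixture())
  expect_equal(flt$species, "A")
  rep <- flt$report
  expect_equal(rep$reason[rep$species_id == "B"], "too_few_seedlings")
  expect_equal(rep$reason[rep$species_id == "C"], "too_few_stations")
  expect_equal(rep$reason[rep$species_id == "D"],
               "insufficient_density_variation")
  expect_equal(rep$n_stations[rep$species_id == "A"], 12L)
  expect_equal(rep$n_seedlings[rep$species_id == "B"], 4)
})

test_that("an empty filter result aborts with a message", {
  dat <- filter_fixture()
  rule <- species_filter_rule(min_stations = 50)
  expect_error(filter_species(dat, rule), "no species")
})

test_that("moment matching reproduces the stated closed forms", {
  # trap pair with mean 8 and sample variance 16
  e <- trap_moments_to_lognormal(8 - sqrt(8), 8 + sqrt(8))
  expect_equal(e$sigma^2, log(1.25), tolerance = 1e-10)
  expect_equal(e$mu, 1.96787, tolerance = 1e-5)
  # zero seeds but 4 seedlings: impute m = v = 4
  e2 <- trap_moments_to_lognormal(0, 0, seedlings = 4)
  expect_equal(e2$sigma^2, log(1.25), tolerance = 1e-10)
  expect_equal(e2$mu, 1.27472, tolerance = 1e-5)
  expect_equal(e2$provenance, "imputed_from_seedlings")
  # agreeing traps hit the variance floor but keep sigma positive
  e3 <- trap_moments_to_lognormal(5, 5)
  expect_gt(e3$sigma, 0)
  expect_equal(e3$sigma^2, log(1 + 0.25 / 25), tolerance = 1e-10)
  # no seeds, no seedlings: uninformative
  e4 <- trap_moments_to_lognormal(0, 0, 0)
  expect_equal(e4$provenance, "uninformative")
  expect_true(is.na(e4$mu))
})

test_that("the implied log-normal matches the target moments exactly", {
  set.seed(31)
  t1 <- stats::rpois(200, 6)
  t2 <- stats::rpois(200, 6)
  sl <- stats::rpois(200, 2)
  e <- trap_moments_to_lognormal(t1, t2, sl)
  ok <- e$provenance != "uninformative"
  m <- (t1 + t2) / 2
  v <- (t1 - t2)^2 / 2
  m[m == 0] <- sl[m == 0]
  v[e$provenance == "imputed_from_seedlings"] <-
    sl[e$provenance == "imputed_from_seedlings"]
  v <- pmax(v, 0.25)
  ln_mean <- exp(e$mu + e$sigma^2 / 2)
  ln_var <- (exp(e$sigma^2) - 1) * exp(2 * e$mu + e$sigma^2)
  expect_equal(ln_mean[ok], m[ok], tolerance = 1e-10)
  expect_equal(ln_var[ok], v[ok], tolerance = 1e-10)
})

test_that("latent priors cover exactly the informative station pairs", {
  sim <- tiny_dataset()
  flt <- filter_species(sim$data, species_filter_rule(min_stations = 2,
                                                      min_density_fold = 1.5,
                                                      min_seedlings = 2))
  pr <- latent_seed_priors(sim$data, flt$species)
  expect_true(all(pr$provenance %in% c("from_traps",
                                       "imputed_from_seedlings")))
  expect_true(all(pr$sigma > 0))
  # imputed rows have zero trap counts and positive seedlings
  imp <- pr[pr$provenance == "imputed_from_seedlings", ]
  if (nrow(imp)) {
    expect_true(all(imp$trap1 == 0 & imp$trap2 == 0 & imp$seedlings > 0))
  }
  # every pair with seeds or seedlings for a retained species is present
  sp1 <- flt$species[1]
  tr <- sim$data$traps
  sl <- sim$data$seedlings
  want <- union(tr$station_id[tr$species_id == sp1],
                sl$station_id[sl$species_id == sp1])
  expect_setequal(pr$station_id[pr$species_id == sp1], want)
})
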