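test_that("inverse Simpson and exponentiated Shannon match closed forms", {
  p <- c(5, 3, 2) / 10
  expect_equal(inverse_simpson(c(5, 3, 2)), 1 / sum(p^2), tolerance = 1e-12)
  expect_equal(inverse_simpson(c(5, 3, 2)), 2.6316, tolerance = 1e-4)
  expect_equal(exp_shannon(c(5, 3, 2)), exp(-sum(p * log(p))),
               tolerance = 1e-12)
  expect_equal(exp_shannon(c(5, 3, 2)), 2.8001, tolerance = 1e-4)
  # k equally common species have k effective species by any order
  for (k in c(2, 5, 9)) {
    expect_equal(inverse_simpson(rep(7, k)), k, tolerance = 1e-12)
    expect_equal(exp_shannon(rep(7, k)), k, tolerance = 1e-12)
  }
  expect_equal(inverse_simpson(c(0, 12, 0)), 1)
  expect_equal(exp_shannon(12), 1)
  expect_true(is.na(inverse_simpson(integer(0))))
  expect_true(is.na(exp_shannon(c(0, 0))))
  expect_error(inverse_simpson(c(-1, 2)), "non-negative")
})

test_that("rarefied richness equals the hypergeometric expectation", {
  # (2,2) rarefied to 2: brute force over all C(4,2) = 6 subsamples
  expect_equal(rarefied_richness(c(2, 2), 2), 5 / 3, tolerance = 1e-12)
  # closed form on a random vector
  v <- c(6, 3, 1, 1)
  N <- sum(v)
  n <- 4
  closed <- sum(1 - choose(N - v, n) / choose(N, n))
  expect_equal(rarefied_richness(v, n), closed, tolerance = 1e-12)
  # full sample returns observed richness
  expect_equal(rarefied_richness(v, N), 4, tolerance = 1e-12)
  # rarefying beyond the sample is undefined
  expect_true(is.na(rarefied_richness(c(1, 1), 5)))
  expect_true(is.na(rarefied_richness(c(0, 0), 1)))
})

test_that("rarefied richness agrees with a Monte-Carlo subsampling oracle", {
  set.seed(71)
  for (i in 1:5) {
    v <- stats::rpois(4, 3) + c(1, 0, 0, 0)
    n <- min(3, sum(v))
    oracle <- mc_rarefy(v, n, reps = 4000)
    expect_lt(abs(rarefied_richness(v, n) - oracle["mean"]),
              3 * oracle["se"] + 1e-9)
  }
})

test_that("indices are invariant to relabeling and count scaling", {
  set.seed(5)
  for (i in 1:20) {
    v <- stats::rpois(8, 4)
    if (sum(v) == 0) v[1] <- 1
    perm <- sample(v)
    expect_equal(inverse_simpson(v), inverse_simpson(perm), tolerance = 1e-12)
    expect_equal(exp_shannon(v), exp_shannon(perm), tolerance = 1e-12)
    expect_equal(inverse_simpson(v), inverse_simpson(3L * v),
                 tolerance = 1e-12)
    expect_equal(exp_shannon(v), exp_shannon(3L * v), tolerance = 1e-12)
  }
})

test_that("diversity_table computes per-plot and pooled-trap values", {
  sim <- tiny_dataset()
  dtab <- diversity_table(sim$data)
  expect_setequal(unique(dtab$unit_kind), c("seedling", "seed"))
  expect_equal(sum(dtab$unit_kind == "seedling"),
               3L * nrow(sim$data$plots))
  expect_equal(sum(dtab$unit_kind == "seed"), 3L * nrow(sim$data$stations))
  # spot-check one plot against the scalar implementations
  pid <- sim$data$plots$plot_id[4]
  cnt <- plot_counts(sim$data, pid)
  expect_equal(dtab$value[dtab$unit_id == pid &
                            dtab$index == "inverse_simpson"],
               inverse_simpson(cnt))
  expect_equal(dtab$value[dtab$unit_id == pid &
                            dtab$index == "rarefied_richness"],
               rarefied_richness(cnt, 2))
  # seed diversity pools the two traps of a station
  sid <- sim$data$stations$station_id[1]
  tr <- sim$data$traps[sim$data$traps$station_id == sid, ]
  pooled <- tapply(tr$count, tr$species_id, sum)
  expect_equal(dtab$value[dtab$unit_id == sid & dtab$index == "exp_shannon"],
               exp_shannon(pooled))
})

test_that("pool_controls averages the two unsprayed plots", {
  base <- data.frame(
    unit_id = paste0("P", 1:5), unit_kind = "seedling", station_id = "S1",
    treatment = c("control", "water", "fungicide", "insecticide", "both"),
    edge_category = "E0", index = "inverse_simpson",
    value = c(3.0, 2.0, 4.1, 5.0, 6.0), stringsAsFactors = FALSE)
  out <- pool_controls(base)
  expect_equal(out$value[out$treatment == "Control"], 2.5)
  expect_equal(out$value[out$treatment == "fungicide"], 4.1)
  expect_equal(nrow(out), 4L)

  same <- base
  same$value[1:2] <- 4.1
  expect_equal(pool_controls(same)$value[1], 4.1)

  # missing water plot: single value used, flagged
  nowater <- base[-2, ]
  out2 <- pool_controls(nowater)
  ctl <- out2[out2$treatment == "Control", ]
  expect_equal(ctl$value, 3.0)
  expect_equal(ctl$flag, "single_control_value")
})
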