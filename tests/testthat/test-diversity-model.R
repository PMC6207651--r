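# build a synthetic diversity_table with known Gaussian structure
gaussian_dtable <- function(seed, n_stations = 60, seed_coef = 0.4,
                            cell_shift = NULL, resid_sd = 0.5) {
  set.seed(seed)
  stations <- sprintf("S%03d", seq_len(n_stations))
  edge <- sample(edge_levels(), n_stations, replace = TRUE)
  stn_eff <- stats::rnorm(n_stations, 0, 0.5)
  seed_div <- stats::rnorm(n_stations, 5, 1)
  trts <- c("control", "water", "fungicide", "insecticide", "both")
  rows <- expand.grid(station = seq_len(n_stations), treatment = trts,
                      stringsAsFactors = FALSE)
  shift <- rep(0, nrow(rows))
  if (!is.null(cell_shift))
    shift <- cell_shift(edge[rows$station], rows$treatment)
  value <- 2 + seed_coef * seed_div[rows$station] + stn_eff[rows$station] +
    shift + stats::rnorm(nrow(rows), 0, resid_sd)
  sl <- data.frame(unit_id = paste0(stations[rows$station], "_", rows$treatment),
                   unit_kind = "seedling",
                   station_id = stations[rows$station],
                   treatment = rows$treatment,
                   edge_category = edge[rows$station],
                   index = "inverse_simpson", value = value,
                   stringsAsFactors = FALSE)
  sd <- data.frame(unit_id = stations, unit_kind = "seed",
                   station_id = stations, treatment = NA_character_,
                   edge_category = edge, index = "inverse_simpson",
                   value = seed_div, stringsAsFactors = FALSE)
  rbind(sl, sd)
}

test_that("the seed-diversity coefficient is recovered with valid CIs", {
  hits <- vapply(1:20, function(s) {
    fit <- suppressWarnings(fit_diversity_model(gaussian_dtable(s)))
    sc <- fit$seed_coef
    abs(sc["estimate"] - 0.4) <= 1.96 * sc["se"]
  }, logical(1))
  expect_gte(sum(hits), 16)
})

test_that("a strong single-cell effect is detected and lettered", {
  shift <- function(edge, trt) {
    ifelse(edge == "E3" & trt %in% c("control", "water"), 2.5, 0)
  }
  fit <- suppressWarnings(
    fit_diversity_model(gaussian_dtable(1, cell_shift = shift)))
  l3 <- fit$letters[fit$letters$group == "E3", ]
  ctl <- l3$letters[l3$treatment == "Control"]
  fng <- l3$letters[l3$treatment == "fungicide"]
  # Control carries a letter no pesticide cell shares
  expect_false(grepl(substr(ctl, 1, 1), fng))
  con <- fit$contrasts
  r <- con[con$edge_category == "E3" & grepl("Control", con$contrast) &
             grepl("fungicide", con$contrast), ]
  expect_lt(r$p, 0.05)
})

test_that("a constant response yields zero contrasts and uniform letters", {
  d <- gaussian_dtable(2, seed_coef = 0, resid_sd = 0.5)
  d$value[d$unit_kind == "seedling"] <- 3.7
  fit <- suppressWarnings(fit_diversity_model(d))
  expect_true(all(abs(fit$contrasts$estimate) < 1e-8))
  for (g in unique(fit$letters$group)) {
    lg <- fit$letters$letters[fit$letters$group == g]
    expect_true(length(unique(lg)) == 1)
  }
})

test_that("insert-and-absorb letters separate exactly the significant pairs", {
  sig <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
  sig["A", "C"] <- sig["C", "A"] <- TRUE
  l <- edgecndd:::insert_absorb_letters(sig)
  expect_equal(unname(l), c("a", "ab", "b"))
  # all different
  sig[] <- TRUE; diag(sig) <- FALSE
  l2 <- edgecndd:::insert_absorb_letters(sig)
  expect_equal(anyDuplicated(l2), 0L)
  # none different
  sig[] <- FALSE
  l3 <- edgecndd:::insert_absorb_letters(sig)
  expect_true(all(l3 == l3[1]))
})

test_that("null light effects are estimated near zero", {
  hits <- vapply(1:10, function(s) {
    d <- gaussian_dtable(s + 100)
    sl <- d[d$unit_kind == "seedling", ]
    light <- data.frame(plot_id = sl$unit_id,
                        light = stats::runif(nrow(sl), 5, 30))
    fit <- suppressWarnings(fit_light_model(d, light))
    abs(fit$light_coef["estimate"]) <= 2 * fit$light_coef["se"]
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("degenerate light covariates are flagged", {
  d <- gaussian_dtable(3)
  sl <- d[d$unit_kind == "seedling", ]
  const <- data.frame(plot_id = sl$unit_id, light = 10)
  expect_warning(fit0 <- fit_light_model(d, const), "constant")
  expect_true(is.na(fit0$light_coef["estimate"]))
  # light that duplicates a treatment dummy makes the design singular
  coll <- data.frame(plot_id = sl$unit_id,
                     light = as.numeric(sl$treatment == "fungicide"))
  expect_warning(suppressMessages(fit_light_model(d, coll)),
                 "condition number|near-singular|rank")
})

test_that("plots without defined diversity are dropped and counted", {
  sim <- tiny_dataset()
  dtab <- diversity_table(sim$data)
  st1 <- sim$data$stations$station_id[1]
  dtab$value[dtab$unit_kind == "seedling" & dtab$station_id == st1] <- NA
  fit <- suppressWarnings(fit_diversity_model(dtab))
  expect_gte(fit$n_dropped, 1)
})
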