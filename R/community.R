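#' Default density-dependence slope matrix
#'
#' Slopes `b` of the power-law seed-to-seedling transition
#' `R = a * S^b` per edge-distance category (rows) and analysis cell
#' (columns).  `b = 1` means no conspecific negative density
#' dependence (CNDD); smaller `b` means stronger CNDD.  The default
#' emulates the pattern the analysis is designed to detect: moderate
#' CNDD everywhere, strongest in the forest interior (E3) under
#' natural enemy pressure, and weakened by pesticides only at E3.
#'
#' @param edges Edge categories (rows).
#' @param cells Analysis cells (columns); `Control` covers both the
#'   untreated and water-sprayed plots.
#' @return Numeric matrix with `edges` rownames and `cells` colnames.
#' @export
default_b_matrix <- function(edges = edge_levels(),
                             cells = c("Control", "fungicide",
                                       "insecticide", "both")) {
  b <- matrix(0.85, nrow = length(edges), ncol = length(cells),
              dimnames = list(edges, cells))
  if ("E3" %in% edges) {
    b["E3", ] <- 0.95
    if ("Control" %in% cells) b["E3", "Control"] <- 0.60
  }
  b
}

#' Community and recruitment parameters for the simulator
#'
#' Ground-truth parameters of the synthetic community: the species
#' relative-abundance law, among-station variation in latent seed
#' density, the per-species baseline transition probability `a`, the
#' density-dependence slope matrix `b`, interspecific slope
#' heterogeneity, and negative-binomial recruitment noise.
#'
#' Latent seed density of species `s` at station `j` is
#' `lambda[j, s] ~ logNormal` with species mean
#' `m_s = total_seed_density * p_s` (so `E[lambda] = m_s`) and log-SD
#' `seed_density_lognormal_sd`.  Each trap catches an independent
#' `Poisson(lambda)` count.  Recruits in a plot follow
#' `NegBin(mean = a_s * lambda^b, size = nb_dispersion)` where
#' `b = b_matrix[edge, cell] + u_s` and `u_s ~ Normal(0,
#' species_slope_sd)`.
#'
#' @param n_species Number of species in the community.
#' @param abundance List describing the relative-abundance law: either
#'   `list(model = "logseries", x = <0..1>)` (Fisher log-series;
#'   larger `x` gives a longer rare-species tail) or
#'   `list(model = "lognormal", sdlog = <positive>)`.
#' @param total_seed_density Expected community-wide seed rain, seeds
#'   per m^2 per year, split across species by relative abundance.
#' @param seed_density_lognormal_sd Log-scale SD of among-station
#'   variation in latent seed density (seed rain is strongly
#'   spatially aggregated; 1.0 is typical of wet tropical forest).
#' @param a_mean,a_logit_sd Mean and logit-scale SD of the per-species
#'   baseline seed-to-seedling transition probability `a_s` in (0, 1].
#' @param b_matrix Slope matrix, see [default_b_matrix()].
#' @param species_slope_sd SD of per-species deviations `u_s` around
#'   the cell-level slope (interspecific variation in CNDD).
#' @param nb_dispersion Negative-binomial size parameter `phi` (> 0)
#'   shared across species; smaller values mean more overdispersion.
#' @param treatment_a_multiplier Optional named multipliers on `a` per
#'   treatment, for sensitivity runs in which pesticides also change
#'   the baseline transition rate; defaults to all 1 (treatments act
#'   through `b` only).
#' @param rng_seed Integer seed; identical seeds reproduce simulated
#'   tables bit-for-bit.
#'
#' @return An object of class `community_params`.
#' @export
community_params <- function(n_species = 40,
                             abundance = list(model = "logseries", x = 0.995),
                             total_seed_density = 600,
                             seed_density_lognormal_sd = 1.0,
                             a_mean = 0.3,
                             a_logit_sd = 0.75,
                             b_matrix = default_b_matrix(),
                             species_slope_sd = 0.2,
                             nb_dispersion = 5,
                             treatment_a_multiplier = NULL,
                             rng_seed = 1L) {
  stopifnot(n_species >= 1, total_seed_density > 0,
            seed_density_lognormal_sd >= 0,
            a_mean > 0, a_mean <= 1, a_logit_sd >= 0,
            is.matrix(b_matrix), all(is.finite(b_matrix)),
            species_slope_sd >= 0, nb_dispersion > 0)
  abundance$model <- match.arg(abundance$model, c("logseries", "lognormal"))
  if (abundance$model == "logseries") {
    abundance$x <- abundance$x %||% 0.995
    stopifnot(abundance$x > 0, abundance$x < 1)
  } else {
    abundance$sdlog <- abundance$sdlog %||% 1.5
    stopifnot(abundance$sdlog >= 0)
  }
  if (is.null(rownames(b_matrix)) || is.null(colnames(b_matrix)))
    stop("b_matrix needs edge rownames and cell colnames")
  if (!is.null(treatment_a_multiplier)) {
    stopifnot(!is.null(names(treatment_a_multiplier)),
              all(treatment_a_multiplier > 0))
  }
  structure(list(n_species = as.integer(n_species), abundance = abundance,
                 total_seed_density = total_seed_density,
                 seed_density_lognormal_sd = seed_density_lognormal_sd,
                 a_mean = a_mean, a_logit_sd = a_logit_sd,
                 b_matrix = b_matrix, species_slope_sd = species_slope_sd,
                 nb_dispersion = nb_dispersion,
                 treatment_a_multiplier = treatment_a_multiplier,
                 rng_seed = as.integer(rng_seed)),
            class = "community_params")
}

# draw one species abundance from the Fisher log-series pmf
# P(n) = -x^n / (n * log(1 - x)), n = 1, 2, ...
rlogseries <- function(n, x, nmax = 1e6) {
  u <- stats::runif(n)
  k <- rep_len(1L, n)
  cum <- rep_len(-x / log1p(-x), n)
  term <- cum
  todo <- u > cum
  while (any(todo) && max(k) < nmax) {
    term[todo] <- term[todo] * x * k[todo] / (k[todo] + 1)
    k[todo] <- k[todo] + 1L
    cum[todo] <- cum[todo] + term[todo]
    todo <- u > cum
  }
  k
}

draw_relative_abundance <- function(params) {
  ab <- params$abundance
  w <- switch(ab$model,
    logseries = rlogseries(params$n_species, ab$x),
    lognormal = stats::rlnorm(params$n_species, 0, ab$sdlog))
  w / sum(w)
}

#' Simulate latent seed densities and trap counts
#'
#' Draws the ground truth (species relative abundances, per-species
#' baselines, latent station-level seed densities) and the observed
#' seed-trap counts.  Each trap at a station is an independent
#' `Poisson(lambda[j, s])` count of the station's latent density, so a
#' trap pair carries replicate information about `lambda` — the
#' structure the measurement-error correction exploits.
#'
#' @param design An [generate_design()] result.
#' @param params A [community_params()].
#' @param seed Integer seed (defaults to `params$rng_seed`).
#'
#' @return A list with `truth` (class `cndd_truth`: `params`, `species`
#'   table with `rel_abund`, `mean_density`, `a`, `u`, and the
#'   `lambda` station-by-species matrix) and `traps`, a long data
#'   frame of positive trap counts (`station_id`, `trap_id`,
#'   `species_id`, `count`).
#' @export
simulate_seed_rain <- function(design, params, seed = params$rng_seed) {
  stopifnot(inherits(design, "edge_design"),
            inherits(params, "community_params"))
  set.seed(as.integer(seed))
  S <- params$n_species
  sp_id <- sprintf("SP%03d", seq_len(S))
  p <- draw_relative_abundance(params)
  m_s <- params$total_seed_density * p
  a_s <- stats::plogis(stats::qlogis(params$a_mean) +
                         stats::rnorm(S, 0, params$a_logit_sd))
  u_s <- stats::rnorm(S, 0, params$species_slope_sd)

  st <- design$stations$station_id
  J <- length(st)
  sdl <- params$seed_density_lognormal_sd
  lambda <- matrix(stats::rlnorm(J * S,
                                 meanlog = rep(log(m_s), each = J) - sdl^2 / 2,
                                 sdlog = sdl),
                   nrow = J, ncol = S, dimnames = list(st, sp_id))
  lambda[, m_s == 0] <- 0

  tr <- design$traps
  counts <- matrix(stats::rpois(nrow(tr) * S, lambda[tr$station_id, ]),
                   nrow = nrow(tr))
  pos <- which(counts > 0, arr.ind = TRUE)
  traps <- data.frame(station_id = tr$station_id[pos[, 1]],
                      trap_id = tr$trap_id[pos[, 1]],
                      species_id = sp_id[pos[, 2]],
                      count = counts[pos],
                      stringsAsFactors = FALSE)
  traps <- traps[order(traps$station_id, traps$trap_id, traps$species_id), ]
  rownames(traps) <- NULL

  truth <- structure(list(params = params,
                          species = data.frame(species_id = sp_id,
                                               rel_abund = p,
                                               mean_density = m_s,
                                               a = a_s, u = u_s,
                                               stringsAsFactors = FALSE),
                          lambda = lambda),
                     class = "cndd_truth")
  list(truth = truth, traps = traps)
}

#' Simulate seedling recruitment in treated plots
#'
#' Draws recruit counts per plot and species from the power-law
#' transition `R ~ NegBin(mean = a_s * lambda^b, size = phi)` with
#' `b = b_matrix[edge, cell] + u_s`.  Plots at the same station share
#' the station's latent seed density; treatments act only through `b`
#' (and optionally through a multiplier on `a`).  Zero latent density
#' yields zero expected recruits regardless of `b`.
#'
#' @param truth Ground truth from [simulate_seed_rain()].
#' @param design The matching [generate_design()] result.
#' @param seed Integer seed (defaults to `params$rng_seed + 1` so that
#'   seed rain and recruitment use distinct, reproducible streams).
#'
#' @return Long data frame of positive recruit counts (`plot_id`,
#'   `station_id`, `treatment`, `species_id`, `recruits`).
#' @export
simulate_recruitment <- function(truth, design,
                                 seed = truth$params$rng_seed + 1L) {
  stopifnot(inherits(truth, "cndd_truth"), inherits(design, "edge_design"))
  params <- truth$params
  set.seed(as.integer(seed))

  b_mat <- params$b_matrix
  pl <- design$plots
  edge <- design$stations$edge_category[match(pl$station_id,
                                              design$stations$station_id)]
  cell <- treatment_cell(pl$treatment)
  miss <- setdiff(unique(cell), colnames(b_mat))
  if (length(miss))
    stop("b_matrix lacks columns for cells: ", paste(miss, collapse = ", "))
  miss <- setdiff(unique(edge), rownames(b_mat))
  if (length(miss))
    stop("b_matrix lacks rows for edges: ", paste(miss, collapse = ", "))

  S <- params$n_species
  sp <- truth$species
  lam <- truth$lambda[pl$station_id, , drop = FALSE]
  b_cell <- matrix(b_mat[cbind(edge, cell)], nrow = nrow(pl), ncol = S)
  b_eff <- b_cell + matrix(sp$u, nrow = nrow(pl), ncol = S, byrow = TRUE)
  a_eff <- matrix(sp$a, nrow = nrow(pl), ncol = S, byrow = TRUE)
  if (!is.null(params$treatment_a_multiplier)) {
    mult <- params$treatment_a_multiplier[pl$treatment]
    mult[is.na(mult)] <- 1
    a_eff <- a_eff * as.numeric(mult)
  }
  mu <- ifelse(lam > 0, a_eff * lam^b_eff, 0)
  r <- matrix(stats::rnbinom(length(mu), mu = mu, size = params$nb_dispersion),
              nrow = nrow(pl))
  pos <- which(r > 0, arr.ind = TRUE)
  out <- data.frame(plot_id = pl$plot_id[pos[, 1]],
                    station_id = pl$station_id[pos[, 1]],
                    treatment = pl$treatment[pos[, 1]],
                    species_id = sp$species_id[pos[, 2]],
                    recruits = r[pos],
                    stringsAsFactors = FALSE)
  out <- out[order(out$plot_id, out$species_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: lays out the design, simulates seed rain and
#' recruitment, and packages the observed tables as an `edge_data`
#' object alongside the ground truth.
#'
#' @param config A [design_config()].
#' @param params A [community_params()].
#' @return List with `data` (class `edge_data`) and `truth`.
#' @export
simulate_dataset <- function(config = design_config(),
                             params = community_params()) {
  design <- generate_design(config, seed = params$rng_seed)
  rain <- simulate_seed_rain(design, params)
  seedlings <- simulate_recruitment(rain$truth, design)
  data <- edge_data(stations = design$stations,
                    plots = design$plots[, c("plot_id", "station_id",
                                             "treatment")],
                    traps = rain$traps, seedlings = seedlings,
                    species = rain$truth$species$species_id,
                    traps_per_station = config$traps_per_station)
  list(data = data, truth = rain$truth)
}
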