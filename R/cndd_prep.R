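#' Species-inclusion rule for the CNDD analysis
#'
#' A species enters the density-dependence model only if its data can
#' inform a slope: it must occur (as seeds or seedlings) in at least
#' `min_stations` stations, show at least `min_density_fold` variation
#' in station-level seed density, and have at least `min_seedlings`
#' seedlings in total.
#'
#' @param min_stations Minimum stations of occurrence (default 10).
#' @param min_density_fold Minimum max/min ratio of positive
#'   station-level seed densities (default 3).
#' @param min_seedlings Minimum total seedlings (default 5).
#' @return An object of class `species_filter_rule`.
#' @export
species_filter_rule <- function(min_stations = 10, min_density_fold = 3,
                                min_seedlings = 5) {
  stopifnot(min_stations > 0, min_density_fold > 0, min_seedlings > 0)
  structure(list(min_stations = min_stations,
                 min_density_fold = min_density_fold,
                 min_seedlings = min_seedlings),
            class = "species_filter_rule")
}

#' Apply the species-inclusion rule
#'
#' Station-level seed density defaults to the trap-pair mean (the two
#' traps sample the same station); the fold-change ratio is taken over
#' stations with positive density only, so a species seen at fewer
#' than two stations with seeds cannot satisfy the fold criterion.
#'
#' @param data An [edge_data()] object.
#' @param rule A [species_filter_rule()].
#' @param density_basis How station seed density is computed for the
#'   fold criterion: trap-pair mean (default), per-trap maximum, or
#'   station sum.
#' @return List with `species` (retained ids) and `report`, a data
#'   frame with one row per species: occupancy, fold change, seedling
#'   total, `retained`, and the first failed criterion in `reason`.
#' @export
filter_species <- function(data, rule = species_filter_rule(),
                           density_basis = c("pair_mean", "trap_max",
                                             "station_sum")) {
  stopifnot(inherits(data, "edge_data"),
            inherits(rule, "species_filter_rule"))
  density_basis <- match.arg(density_basis)

  report <- do.call(rbind, lapply(data$species, function(sp) {
    tr <- data$traps[data$traps$species_id == sp, , drop = FALSE]
    sl <- data$seedlings[data$seedlings$species_id == sp, , drop = FALSE]
    seed_st <- unique(tr$station_id)
    stn <- unique(c(seed_st, sl$station_id))
    dens <- if (nrow(tr)) {
      per_trap <- tapply(tr$count, tr$station_id, sum)
      switch(density_basis,
             pair_mean = per_trap / data$traps_per_station,
             trap_max = tapply(tr$count,
                               interaction(tr$station_id, tr$trap_id,
                                           drop = TRUE), sum),
             station_sum = per_trap)
    } else numeric(0)
    dens <- dens[dens > 0]
    fold <- if (length(dens) >= 2) max(dens) / min(dens) else NA_real_
    n_seedlings <- sum(sl$recruits)
    reason <- ""
    if (length(stn) < rule$min_stations) {
      reason <- "too_few_stations"
    } else if (is.na(fold) || fold < rule$min_density_fold) {
      reason <- "insufficient_density_variation"
    } else if (n_seedlings < rule$min_seedlings) {
      reason <- "too_few_seedlings"
    }
    data.frame(species_id = sp, n_stations = length(stn),
               density_fold = fold, n_seedlings = n_seedlings,
               retained = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  keep <- report$species_id[report$retained]
  if (!length(keep))
    stop("species filter retained no species; cannot estimate CNDD")
  list(species = keep, report = report)
}

#' Moment-matched log-normal prior for latent seed density
#'
#' Converts a pair of adjacent trap counts into the log-normal
#' distribution whose mean and variance equal the pair's sample mean
#' `m` and (floored) sample variance `v'`:
#' `sigma^2 = log(1 + v'/m^2)`, `mu = log(m) - sigma^2/2`.  When both
#' traps are empty but seedlings of the species occurred at the
#' station, the seedling count substitutes for both moments
#' (`m = v' = seedlings`) — a conservative imputation that biases
#' against detecting density dependence.  When both traps are empty
#' and no seedlings occurred, the pair carries no information and is
#' dropped.  A variance floor keeps `sigma > 0` when the two traps
#' agree exactly.
#'
#' @param trap1,trap2 Counts in the two traps (vectorised).
#' @param seedlings Total seedlings of the species at the station.
#' @param var_floor Lower bound on the variance (default 0.25, below
#'   one-seed resolution).
#' @return Data frame with `mu`, `sigma` (log scale), `provenance`
#'   (`from_traps`, `imputed_from_seedlings` or `uninformative`);
#'   `mu`/`sigma` are `NA` for uninformative pairs.
#' @examples
#' trap_moments_to_lognormal(4, 12)   # m = 8, v = 32
#' trap_moments_to_lognormal(0, 0, seedlings = 4)
#' @export
trap_moments_to_lognormal <- function(trap1, trap2, seedlings = 0,
                                      var_floor = 0.25) {
  stopifnot(all(trap1 >= 0), all(trap2 >= 0), all(seedlings >= 0),
            var_floor > 0)
  n <- max(length(trap1), length(trap2), length(seedlings))
  trap1 <- rep_len(trap1, n); trap2 <- rep_len(trap2, n)
  seedlings <- rep_len(seedlings, n)

  m <- (trap1 + trap2) / 2
  v <- (trap1 - trap2)^2 / 2          # two-point sample variance (n - 1)
  provenance <- rep("from_traps", n)
  imput <- m == 0 & seedlings > 0
  drop <- m == 0 & seedlings == 0
  m[imput] <- seedlings[imput]
  v[imput] <- seedlings[imput]
  provenance[imput] <- "imputed_from_seedlings"
  provenance[drop] <- "uninformative"

  v <- pmax(v, var_floor)
  sigma2 <- log(1 + v / m^2)
  mu <- log(m) - sigma2 / 2
  mu[drop] <- NA_real_
  sigma2[drop] <- NA_real_
  data.frame(mu = mu, sigma = sqrt(sigma2), provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Latent seed-density priors for every modelled station x species pair
#'
#' Assembles trap pairs and station-level seedling totals for the
#' retained species and applies [trap_moments_to_lognormal()].
#'
#' @param data An [edge_data()] object.
#' @param species Species to include (typically [filter_species()]
#'   output).
#' @param var_floor Passed through to the moment matching.
#' @return Data frame with one row per (station, species):
#'   `station_id`, `species_id`, `trap1`, `trap2`, `seedlings`, `mu`,
#'   `sigma`, `provenance`.  Uninformative pairs are excluded.
#' @export
latent_seed_priors <- function(data, species, var_floor = 0.25) {
  stopifnot(inherits(data, "edge_data"))
  if (data$traps_per_station != 2)
    stop("the measurement-error correction expects exactly 2 traps/station")
  grid <- expand.grid(station_id = data$stations$station_id,
                      species_id = species, stringsAsFactors = FALSE)
  tr <- data$traps[data$traps$species_id %in% species, ]
  key <- function(st, sp, trap) paste(st, sp, trap)
  t1 <- tr[tr$trap_id == 1, ]; t2 <- tr[tr$trap_id == 2, ]
  grid$trap1 <- t1$count[match(paste(grid$station_id, grid$species_id),
                               paste(t1$station_id, t1$species_id))]
  grid$trap2 <- t2$count[match(paste(grid$station_id, grid$species_id),
                               paste(t2$station_id, t2$species_id))]
  grid$trap1[is.na(grid$trap1)] <- 0
  grid$trap2[is.na(grid$trap2)] <- 0
  sl <- data$seedlings[data$seedlings$species_id %in% species, ]
  agg <- tapply(sl$recruits, paste(sl$station_id, sl$species_id), sum)
  grid$seedlings <- agg[paste(grid$station_id, grid$species_id)]
  grid$seedlings[is.na(grid$seedlings)] <- 0

  mm <- trap_moments_to_lognormal(grid$trap1, grid$trap2, grid$seedlings,
                                  var_floor = var_floor)
  out <- cbind(grid, mm)
  out <- out[out$provenance != "uninformative", , drop = FALSE]
  rownames(out) <- NULL
  out
}
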