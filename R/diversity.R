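#' Hill-number diversity indices
#'
#' The three indices used throughout the package, all in
#' effective-species units: inverse Simpson (Hill number of order 2),
#' exponentiated Shannon (order 1) and hypergeometric rarefied
#' richness.  An assemblage with no individuals has no defined
#' diversity and yields `NA`.
#'
#' @param counts Non-negative integer vector of per-species abundances.
#' @return A single numeric value, or `NA` when undefined.
#' @name diversity_indices
NULL

#' @describeIn diversity_indices `1 / sum(p_i^2)`.
#' @export
inverse_simpson <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) < 1) return(NA_real_)
  as.numeric(vegan::diversity(counts, index = "invsimpson"))
}

#' @describeIn diversity_indices `exp(-sum(p_i * log(p_i)))`.
#' @export
exp_shannon <- function(counts) {
  counts <- check_counts(counts)
  if (sum(counts) < 1) return(NA_real_)
  exp(as.numeric(vegan::diversity(counts, index = "shannon")))
}

#' @describeIn diversity_indices Expected species count in a subsample
#'   of `n` individuals drawn without replacement
#'   (`sum_i 1 - choose(N - N_i, n) / choose(N, n)`); `NA` when the
#'   assemblage holds fewer than `n` individuals, since rarefying
#'   beyond the sample would impute a downward-biased value.
#' @param n Rarefaction sample size (2 for seedling plots and 5 for
#'   seed assemblages in the reference analysis).
#' @export
rarefied_richness <- function(counts, n) {
  counts <- check_counts(counts)
  stopifnot(length(n) == 1, n >= 1)
  if (sum(counts) < n) return(NA_real_)
  # rarefy's singleton heuristic warning targets whole community matrices,
  # not single assemblages
  v <- suppressWarnings(vegan::rarefy(counts, sample = n))
  as.numeric(v)
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts
}

diversity_index_names <- function() {
  c("rarefied_richness", "inverse_simpson", "exp_shannon")
}

apply_index <- function(counts, index, rarefy_n) {
  switch(index,
         rarefied_richness = rarefied_richness(counts, rarefy_n),
         inverse_simpson = inverse_simpson(counts),
         exp_shannon = exp_shannon(counts),
         stop("unknown index: ", index))
}

#' Per-plot and per-station diversity table
#'
#' Computes the three diversity indices for every seedling plot and for
#' every station's seed assemblage.  Seed assemblages pool the
#' station's two traps (summed counts), since both traps sample the
#' same station.  Units with no individuals, and units below the
#' rarefaction size, carry `NA` for the affected index.
#'
#' @param data An [edge_data()] object.
#' @param indices Which indices to compute.
#' @param rarefy_n_seedlings,rarefy_n_seeds Rarefaction sample sizes
#'   (defaults 2 and 5, matching the reference analysis).
#' @return Long data frame: `unit_id`, `unit_kind` (`"seedling"` plot
#'   or `"seed"` station), `station_id`, `treatment` (`NA` for seeds),
#'   `edge_category`, `index`, `value`.
#' @export
diversity_table <- function(data, indices = diversity_index_names(),
                            rarefy_n_seedlings = 2, rarefy_n_seeds = 5) {
  stopifnot(inherits(data, "edge_data"))
  indices <- match.arg(indices, diversity_index_names(), several.ok = TRUE)
  edge_of <- stats::setNames(data$stations$edge_category,
                             data$stations$station_id)

  sl <- data$seedlings
  plot_mat <- count_matrix(data$plots$plot_id, data$species,
                           sl$plot_id, sl$species_id, sl$recruits)
  plot_rows <- index_block(plot_mat, indices, rarefy_n_seedlings)
  plot_rows$unit_kind <- "seedling"
  plot_rows$station_id <- data$plots$station_id[match(plot_rows$unit_id,
                                                      data$plots$plot_id)]
  plot_rows$treatment <- data$plots$treatment[match(plot_rows$unit_id,
                                                    data$plots$plot_id)]

  tp <- data$traps
  seed_mat <- count_matrix(data$stations$station_id, data$species,
                           tp$station_id, tp$species_id, tp$count)
  seed_rows <- index_block(seed_mat, indices, rarefy_n_seeds)
  seed_rows$unit_kind <- "seed"
  seed_rows$station_id <- seed_rows$unit_id
  seed_rows$treatment <- NA_character_

  out <- rbind(plot_rows, seed_rows)
  out$edge_category <- unname(edge_of[out$station_id])
  rownames(out) <- NULL
  out[, c("unit_id", "unit_kind", "station_id", "treatment", "edge_category",
          "index", "value")]
}

count_matrix <- function(units, species, unit_of, species_of, value) {
  m <- matrix(0, length(units), length(species),
              dimnames = list(units, species))
  if (length(unit_of)) {
    # duplicate (unit, species) rows (e.g. the two traps of a pair) are summed
    agg <- rowsum(value, group = paste(match(unit_of, units),
                                       match(species_of, species)))
    ij <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
    m[ij] <- agg[, 1]
  }
  m
}

# all three indices on every row of a unit x species count matrix
index_block <- function(m, indices, rarefy_n) {
  N <- rowSums(m)
  vals <- lapply(indices, function(ix) {
    v <- switch(ix,
      inverse_simpson = as.numeric(vegan::diversity(m, index = "invsimpson")),
      exp_shannon = exp(as.numeric(vegan::diversity(m, index = "shannon"))),
      rarefied_richness = {
        ok <- N >= rarefy_n
        r <- rep(NA_real_, nrow(m))
        if (any(ok))
          r[ok] <- as.numeric(suppressWarnings(
            vegan::rarefy(m[ok, , drop = FALSE], sample = rarefy_n)))
        r
      })
    v[N < 1] <- NA_real_
    v
  })
  data.frame(unit_id = rep(rownames(m), times = length(indices)),
             index = rep(indices, each = nrow(m)),
             value = unlist(vals), stringsAsFactors = FALSE)
}

#' Collapse control and water plots into a pooled Control value
#'
#' Per station and index, the pooled Control diversity is the
#' arithmetic mean of the untreated-control and water-control plot
#' values; pesticide treatments pass through unchanged.  A station
#' missing one of the two plots (or whose plot value is undefined)
#' uses the single available value and is flagged.
#'
#' @param dtable Seedling rows of a [diversity_table()].
#' @return Data frame with one row per station, analysis-cell
#'   treatment and index: `station_id`, `edge_category`, `treatment`
#'   (`Control`, `fungicide`, `insecticide`, `both`), `index`,
#'   `value`, `flag` (`""` or `"single_control_value"`).
#' @export
pool_controls <- function(dtable) {
  d <- dtable[dtable$unit_kind == "seedling", , drop = FALSE]
  d$cell <- treatment_cell(d$treatment)
  key <- interaction(d$station_id, d$cell, d$index, drop = TRUE)
  pooled <- do.call(rbind, lapply(split(d, key), function(g) {
    ok <- !is.na(g$value)
    flag <- ""
    if (g$cell[1] == "Control" && sum(ok) == 1 && nrow(g) >= 1)
      flag <- "single_control_value"
    data.frame(station_id = g$station_id[1],
               edge_category = g$edge_category[1],
               treatment = g$cell[1], index = g$index[1],
               value = if (any(ok)) mean(g$value[ok]) else NA_real_,
               flag = flag, stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  pooled[order(pooled$station_id, pooled$treatment, pooled$index), ]
}
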