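#' Sampling-design configuration
#'
#' Describes the nested edge-gradient sampling design: locations along
#' forest edges, each holding stations at edge-distance categories E0
#' (0-5 m), E1 (20-30 m) and E2 (50-60 m), plus a limited set of
#' interior stations at E3 (90-100 m) attached to a subset of
#' locations.  Every station carries a fixed number of 1 m^2 seed traps
#' and one 1 m^2 seedling plot per treatment.
#'
#' @param n_locations Number of edge locations.
#' @param replicates_per_distance Stations per location in each of E0,
#'   E1 and E2.
#' @param n_e3_stations Total number of interior (E3) stations across
#'   the landscape; may be 0 to omit the interior band.
#' @param n_e3_locations Number of locations that host E3 stations;
#'   stations are dealt round-robin across them.
#' @param traps_per_station Seed traps per station (2 in the reference
#'   design; the measurement-error correction assumes a trap pair).
#' @param treatments Character vector of plot treatments; each station
#'   receives exactly one plot per treatment.  The full design uses
#'   `c("control", "water", "fungicide", "insecticide", "both")`.
#' @param keep_stations Optional integer: randomly subsample the design
#'   down to this many stations (field campaigns rarely retain every
#'   planned station; the reference landscape kept 146 of 150).
#'
#' @return An object of class `design_config`.
#' @seealso [generate_design()]
#' @export
design_config <- function(n_locations = 15,
                          replicates_per_distance = 3,
                          n_e3_stations = 15,
                          n_e3_locations = 5,
                          traps_per_station = 2,
                          treatments = c("control", "water", "fungicide",
                                         "insecticide", "both"),
                          keep_stations = NULL) {
  stopifnot(n_locations >= 1, replicates_per_distance >= 1,
            n_e3_stations >= 0, traps_per_station >= 1,
            length(treatments) >= 1, !anyDuplicated(treatments))
  treatments <- match.arg(treatments,
                          c("control", "water", "fungicide", "insecticide",
                            "both"),
                          several.ok = TRUE)
  if (n_e3_stations > n_locations * replicates_per_distance)
    stop("n_e3_stations (", n_e3_stations, ") exceeds n_locations x ",
         "replicates_per_distance (",
         n_locations * replicates_per_distance, ")")
  if (n_e3_stations > 0 && n_e3_locations < 1)
    stop("n_e3_locations must be >= 1 when n_e3_stations > 0")
  n_e3_locations <- min(n_e3_locations, n_locations)
  if (!is.null(keep_stations)) {
    total <- 3L * n_locations * replicates_per_distance + n_e3_stations
    if (keep_stations < 1 || keep_stations > total)
      stop("keep_stations must be in [1, ", total, "]")
  }
  structure(list(n_locations = as.integer(n_locations),
                 replicates_per_distance = as.integer(replicates_per_distance),
                 n_e3_stations = as.integer(n_e3_stations),
                 n_e3_locations = as.integer(n_e3_locations),
                 traps_per_station = as.integer(traps_per_station),
                 treatments = treatments,
                 plots_per_station = length(treatments),
                 keep_stations = if (is.null(keep_stations)) NULL
                                 else as.integer(keep_stations)),
            class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("Sampling design:", x$n_locations, "locations x",
      x$replicates_per_distance, "stations in each of E0/E1/E2;",
      x$n_e3_stations, "E3 stations over", x$n_e3_locations, "locations\n")
  cat("Per station:", x$traps_per_station, "seed traps,",
      x$plots_per_station, "plots (",
      paste(x$treatments, collapse = ", "), ")\n")
  if (!is.null(x$keep_stations))
    cat("Subsampled to", x$keep_stations, "stations\n")
  invisible(x)
}

#' Lay out stations, plots and traps for a sampling design
#'
#' Expands a [design_config()] into concrete station, plot and trap
#' tables.  Treatments are assigned to plots in random order within
#' each station; everything else is a deterministic function of the
#' configuration.
#'
#' @param config A [design_config()].
#' @param seed Integer seed controlling treatment randomisation and the
#'   optional station subsample.
#'
#' @return An object of class `edge_design`: a list with data frames
#'   `stations` (`station_id`, `location_id`, `edge_category`,
#'   `replicate`), `plots` (`plot_id`, `station_id`, `treatment`) and
#'   `traps` (`station_id`, `trap_id`), plus the `config`.
#' @examples
#' d <- generate_design(design_config())
#' table(d$stations$edge_category)
#' @export
generate_design <- function(config = design_config(), seed = 1L) {
  stopifnot(inherits(config, "design_config"))
  edges <- c("E0", "E1", "E2")
  loc <- sprintf("L%02d", seq_len(config$n_locations))

  grid <- expand.grid(replicate = seq_len(config$replicates_per_distance),
                      location_id = loc, edge_category = edges,
                      stringsAsFactors = FALSE)
  if (config$n_e3_stations > 0) {
    e3_loc <- rep_len(loc[seq_len(config$n_e3_locations)],
                      config$n_e3_stations)
    e3_rep <- as.integer(stats::ave(seq_along(e3_loc), e3_loc, FUN = seq_along))
    grid <- rbind(grid,
                  data.frame(replicate = e3_rep, location_id = e3_loc,
                             edge_category = "E3", stringsAsFactors = FALSE))
  }
  grid <- grid[order(grid$edge_category, grid$location_id, grid$replicate), ]
  stations <- data.frame(
    station_id = sprintf("ST%03d", seq_len(nrow(grid))),
    location_id = grid$location_id,
    edge_category = grid$edge_category,
    replicate = grid$replicate,
    stringsAsFactors = FALSE)

  set.seed(as.integer(seed))
  if (!is.null(config$keep_stations)) {
    keep <- sort(sample.int(nrow(stations), config$keep_stations))
    stations <- stations[keep, , drop = FALSE]
    rownames(stations) <- NULL
  }

  trt <- do.call(rbind, lapply(stations$station_id, function(sid) {
    data.frame(station_id = sid,
               treatment = sample(config$treatments),
               stringsAsFactors = FALSE)
  }))
  plots <- data.frame(
    plot_id = paste0(trt$station_id, "_P",
                     stats::ave(seq_len(nrow(trt)), trt$station_id,
                                FUN = seq_along)),
    station_id = trt$station_id,
    treatment = trt$treatment,
    stringsAsFactors = FALSE)

  traps <- expand.grid(trap_id = seq_len(config$traps_per_station),
                       station_id = stations$station_id,
                       stringsAsFactors = FALSE)[, c("station_id", "trap_id")]
  traps <- traps[order(traps$station_id, traps$trap_id), ]
  rownames(traps) <- NULL

  structure(list(stations = stations, plots = plots, traps = traps,
                 config = config),
            class = "edge_design")
}

#' @export
print.edge_design <- function(x, ...) {
  cat("edge_design:", nrow(x$stations), "stations,", nrow(x$plots),
      "plots,", nrow(x$traps), "traps\n")
  print(table(x$stations$edge_category))
  invisible(x)
}
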