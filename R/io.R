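#' Container for one edge-gradient dataset
#'
#' Bundles the four observed tables the analyses consume: station
#' metadata, plot metadata, long-format trap counts and long-format
#' seedling counts.  Zero counts are implicit: a (station, trap,
#' species) or (plot, species) combination absent from the long tables
#' is a zero.
#'
#' @param stations Data frame with `station_id`, `location_id`,
#'   `edge_category` (and optionally `replicate`).
#' @param plots Data frame with `plot_id`, `station_id`, `treatment`.
#' @param traps Data frame with `station_id`, `trap_id`, `species_id`,
#'   `count`.
#' @param seedlings Data frame with `plot_id`, `station_id` (optional,
#'   derived), `treatment` (optional), `species_id`, `recruits`.
#' @param species Character vector of all species ids (the observed
#'   union is used if omitted).
#' @param traps_per_station Number of traps at every station (default 2).
#' @return An object of class `edge_data`.
#' @export
edge_data <- function(stations, plots, traps, seedlings, species = NULL,
                      traps_per_station = 2L) {
  seedlings$station_id <- plots$station_id[match(seedlings$plot_id,
                                                 plots$plot_id)]
  seedlings$treatment <- plots$treatment[match(seedlings$plot_id,
                                               plots$plot_id)]
  species <- sort(unique(c(species, traps$species_id, seedlings$species_id)))
  x <- structure(list(stations = stations,
                      plots = plots[, c("plot_id", "station_id", "treatment")],
                      traps = traps,
                      seedlings = seedlings[, c("plot_id", "station_id",
                                                "treatment", "species_id",
                                                "recruits")],
                      species = species,
                      traps_per_station = as.integer(traps_per_station)),
                 class = "edge_data")
  validate_edge_data(x)
  x
}

#' @export
print.edge_data <- function(x, ...) {
  cat("edge_data:", nrow(x$stations), "stations,", nrow(x$plots), "plots,",
      length(x$species), "species\n")
  cat("  trap records:", nrow(x$traps),
      " seedling records:", nrow(x$seedlings), "\n")
  print(table(x$stations$edge_category))
  invisible(x)
}

validate_edge_data <- function(x) {
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(name, ": missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  need(x$stations, c("station_id", "location_id", "edge_category"), "stations")
  need(x$plots, c("plot_id", "station_id", "treatment"), "plots")
  need(x$traps, c("station_id", "trap_id", "species_id", "count"), "traps")
  need(x$seedlings, c("plot_id", "species_id", "recruits"), "seedlings")

  if (anyDuplicated(x$stations$station_id))
    stop("stations: duplicated station_id", call. = FALSE)
  if (anyDuplicated(x$plots$plot_id))
    stop("plots: duplicated plot_id", call. = FALSE)

  bad <- which(!x$stations$edge_category %in% edge_levels())
  if (length(bad))
    stop("stations: row ", bad[1], ": edge_category '",
         x$stations$edge_category[bad[1]], "' not one of ",
         paste(edge_levels(), collapse = "/"), call. = FALSE)
  bad <- which(!x$plots$treatment %in% known_treatments())
  if (length(bad))
    stop("plots: row ", bad[1], ": treatment '", x$plots$treatment[bad[1]],
         "' not one of ", paste(known_treatments(), collapse = "/"),
         call. = FALSE)
  bad <- which(!x$plots$station_id %in% x$stations$station_id)
  if (length(bad))
    stop("plots: row ", bad[1], ": unknown station_id '",
         x$plots$station_id[bad[1]], "'", call. = FALSE)
  bad <- which(!x$traps$station_id %in% x$stations$station_id)
  if (length(bad))
    stop("traps: row ", bad[1], ": unknown station_id '",
         x$traps$station_id[bad[1]], "'", call. = FALSE)
  bad <- which(!x$seedlings$plot_id %in% x$plots$plot_id)
  if (length(bad))
    stop("seedlings: row ", bad[1], ": unknown plot_id '",
         x$seedlings$plot_id[bad[1]], "'", call. = FALSE)
  if (any(x$traps$count < 0) || any(x$traps$count != round(x$traps$count)))
    stop("traps: counts must be non-negative integers", call. = FALSE)
  if (any(x$seedlings$recruits < 0) ||
      any(x$seedlings$recruits != round(x$seedlings$recruits)))
    stop("seedlings: recruits must be non-negative integers", call. = FALSE)
  invisible(x)
}

#' Write a dataset (and optional ground truth) to a directory
#'
#' Writes `stations.csv`, `plots.csv` (one metadata row per plot),
#' `traps.csv`, `seedlings.csv` and, when truth is supplied,
#' `truth.json` with every simulation parameter and the latent density
#' matrix, so parameter-recovery checks can compare estimates against
#' the generating values.
#'
#' @param data An [edge_data()] object.
#' @param dir Output directory (created if needed).
#' @param truth Optional `cndd_truth` from the simulator.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, truth = NULL, overwrite = FALSE) {
  stopifnot(inherits(data, "edge_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("stations.csv", "plots.csv", "traps.csv",
                            "seedlings.csv", "truth.json"))
  exists <- files[file.exists(files)]
  if (length(exists) && !overwrite)
    stop("refusing to overwrite ", paste(basename(exists), collapse = ", "),
         " (use overwrite = TRUE)")
  utils::write.csv(data$stations, files[1], row.names = FALSE)
  utils::write.csv(data$plots, files[2], row.names = FALSE)
  utils::write.csv(data$traps, files[3], row.names = FALSE)
  utils::write.csv(data$seedlings[, c("plot_id", "species_id", "recruits")],
                   files[4], row.names = FALSE)
  if (!is.null(truth)) {
    tr <- list(params = truth$params[setdiff(names(truth$params), "b_matrix")],
               b_matrix = list(values = truth$params$b_matrix,
                               edges = rownames(truth$params$b_matrix),
                               cells = colnames(truth$params$b_matrix)),
               species = truth$species,
               lambda = list(values = truth$lambda,
                             stations = rownames(truth$lambda),
                             species = colnames(truth$lambda)))
    jsonlite::write_json(tr, files[5], digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read and validate a dataset directory
#'
#' Loads the CSV schemas written by [write_dataset()] (or real field
#' data in the same layout), normalises treatment-label case with a
#' warning, enforces referential integrity, and returns an
#' [edge_data()] object.  Validation failures name the file, row and
#' violated rule.
#'
#' @param dir Directory holding `stations.csv`, `plots.csv`,
#'   `traps.csv` and `seedlings.csv`.
#' @param quiet Suppress the row-count message.
#' @return An `edge_data` object; if `truth.json` is present it is
#'   attached as attribute `"truth"`.
#' @export
read_dataset <- function(dir, quiet = FALSE) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing file: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  stations <- rd("stations.csv")
  plots <- rd("plots.csv")
  traps <- rd("traps.csv")
  seedlings <- rd("seedlings.csv")

  if ("treatment" %in% names(plots)) {
    norm <- tolower(plots$treatment)
    changed <- which(norm != plots$treatment & norm %in% known_treatments())
    if (length(changed)) {
      warning("plots.csv: normalised treatment case on ", length(changed),
              " row(s) (e.g. '", plots$treatment[changed[1]], "')")
      plots$treatment[changed] <- norm[changed]
    }
  }
  x <- edge_data(stations = stations, plots = plots, traps = traps,
                 seedlings = seedlings)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj))
    attr(x, "truth") <- jsonlite::read_json(tj, simplifyVector = TRUE)
  if (!quiet)
    message("read ", nrow(stations), " stations, ", nrow(plots), " plots, ",
            nrow(traps), " trap records, ", nrow(seedlings),
            " seedling records from ", dir)
  x
}
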