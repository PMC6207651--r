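#' Build and validate a pipeline configuration
#'
#' Assembles the options of every stage (simulate, diversity, cndd)
#' into one validated object.  All options are checked before any
#' stage runs, and the resolved configuration is echoed into the
#' output directory so a run can be reproduced from its outputs alone.
#'
#' @param simulate `NULL` to read an existing dataset from
#'   `data_dir`, or a list with optional `design` ([design_config()]
#'   fields) and `community` ([community_params()] fields).
#' @param data_dir Directory with an existing dataset (required when
#'   `simulate` is `NULL`).
#' @param diversity List: `indices`, `correction`,
#'   `rarefy_n_seedlings`, `rarefy_n_seeds`.
#' @param cndd `NULL` to skip the CNDD stage, or a list: `filter`
#'   ([species_filter_rule()] fields), plus any [cndd_model_spec()]
#'   arguments, plus optional `run_naive` (logical).
#' @param seed Integer base seed for every stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), data_dir = NULL,
                            diversity = list(), cndd = list(), seed = 1L) {
  if (is.null(simulate) && is.null(data_dir))
    stop("either a simulate block or a data_dir is required")
  cfg <- list(seed = as.integer(seed), data_dir = data_dir)

  if (!is.null(simulate)) {
    cfg$design <- do.call(design_config, simulate$design %||% list())
    cp <- simulate$community %||% list()
    if (!is.null(cp$b_matrix) && !is.matrix(cp$b_matrix))
      cp$b_matrix <- as_b_matrix(cp$b_matrix)
    cp$rng_seed <- cp$rng_seed %||% seed
    cfg$community <- do.call(community_params, cp)
  }

  dv <- diversity %||% list()
  cfg$diversity <- list(
    indices = match.arg(dv$indices %||% diversity_index_names(),
                        diversity_index_names(), several.ok = TRUE),
    correction = match.arg(dv$correction %||% "tukey", c("tukey", "none")),
    rarefy_n_seedlings = dv$rarefy_n_seedlings %||% 2,
    rarefy_n_seeds = dv$rarefy_n_seeds %||% 5)

  if (!is.null(cndd)) {
    cfg$filter <- do.call(species_filter_rule, cndd$filter %||% list())
    sp <- cndd[setdiff(names(cndd), c("filter", "run_naive"))]
    sp$seed <- sp$seed %||% seed
    cfg$cndd <- do.call(cndd_model_spec, sp)
    cfg$run_naive <- isTRUE(cndd$run_naive)
  }
  structure(cfg, class = "pipeline_config")
}

as_b_matrix <- function(x) {
  # YAML represents the matrix as a named list of named rows
  rows <- names(x)
  cols <- names(x[[1]])
  m <- matrix(unlist(x), nrow = length(rows), byrow = TRUE,
              dimnames = list(rows, cols))
  m
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level blocks `simulate` (or
#'   `data_dir`), `diversity`, `cndd` and `seed`.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(simulate = if (isFALSE(y$simulate)) NULL else y$simulate,
                  data_dir = y$data_dir,
                  diversity = y$diversity %||% list(),
                  cndd = if (isFALSE(y$cndd)) NULL else y$cndd %||% list(),
                  seed = y$seed %||% 1L)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional), diversity and CNDD stages, writing
#' every intermediate and a summary report (markdown plus
#' machine-readable JSON) to `out_dir`.  A stage failure halts
#' downstream stages; outputs of completed stages are retained.
#'
#' Outputs: `resolved_config.yaml`, the dataset CSVs (when simulated),
#' `diversity.csv`, `diversity_model.json`, `filter_report.csv`,
#' `cndd_summary.csv`, `cndd_draws.csv`, `diagnostics.json`,
#' `report.md` and `report.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  echo_config(config, file.path(out_dir, "resolved_config.yaml"))
  report <- list(seed = config$seed)

  if (!is.null(config$community)) {
    sim <- simulate_dataset(config$design, config$community)
    data <- sim$data
    write_dataset(data, file.path(out_dir, "data"), truth = sim$truth,
                  overwrite = TRUE)
    message("simulate: ", nrow(data$stations), " stations, ",
            nrow(data$plots), " plots, ", length(data$species), " species")
  } else {
    data <- read_dataset(config$data_dir)
  }
  report$n_stations <- nrow(data$stations)
  report$n_plots <- nrow(data$plots)
  report$n_species <- length(data$species)

  # ---- diversity stage ----
  dv <- config$diversity
  dtab <- diversity_table(data, indices = dv$indices,
                          rarefy_n_seedlings = dv$rarefy_n_seedlings,
                          rarefy_n_seeds = dv$rarefy_n_seeds)
  utils::write.csv(dtab, file.path(out_dir, "diversity.csv"),
                   row.names = FALSE)
  fits <- lapply(dv$indices, function(ix) {
    tryCatch(fit_diversity_model(dtab, index = ix,
                                 correction = dv$correction),
             error = function(e) {
               message("diversity model (", ix, ") failed: ",
                       conditionMessage(e))
               NULL
             })
  })
  names(fits) <- dv$indices
  report$diversity <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    list(cell_means = f$cell_means, contrasts = f$contrasts,
         letters = f$letters, seed_coef = as.list(f$seed_coef),
         n_dropped = f$n_dropped, singular = f$singular)
  })
  jsonlite::write_json(report$diversity,
                       file.path(out_dir, "diversity_model.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  message("diversity: ", length(dv$indices), " indices, ",
          sum(is.na(dtab$value)), " undefined unit values")

  # ---- cndd stage ----
  if (!is.null(config$cndd)) {
    flt <- filter_species(data, config$filter)
    utils::write.csv(flt$report, file.path(out_dir, "filter_report.csv"),
                     row.names = FALSE)
    message("cndd: retained ", length(flt$species), " of ",
            nrow(flt$report), " species")
    fit <- fit_cndd_model(data, flt$species, spec = config$cndd)
    utils::write.csv(fit$summary[, c("cell", "mean_b", "ci_low", "ci_high",
                                     "cndd_flag")],
                     file.path(out_dir, "cndd_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(cndd_draws_long(fit),
                     file.path(out_dir, "cndd_draws.csv"), row.names = FALSE)
    jsonlite::write_json(list(converged = fit$diagnostics$converged,
                              parameters = fit$diagnostics$table,
                              n_obs = fit$n_obs, n_pairs = fit$n_pairs,
                              n_imputed = fit$n_imputed),
                         file.path(out_dir, "diagnostics.json"),
                         digits = NA, auto_unbox = TRUE)
    report$cndd <- list(summary = fit$summary,
                        converged = fit$diagnostics$converged,
                        filter = list(retained = length(flt$species),
                                      total = nrow(flt$report)))
    if (isTRUE(config$run_naive)) {
      nv <- fit_naive_model(data, flt$species, spec = config$cndd)
      utils::write.csv(nv$summary[, c("cell", "mean_b", "ci_low", "ci_high",
                                      "cndd_flag")],
                       file.path(out_dir, "cndd_summary_naive.csv"),
                       row.names = FALSE)
      report$cndd$naive_summary <- nv$summary
    }
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  invisible(report)
}

echo_config <- function(config, path) {
  serial <- rapply(unclass(config), function(x) {
    if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE) else x
  }, classes = "ANY", how = "replace")
  yaml::write_yaml(serial, path)
}

render_report_md <- function(report) {
  ln <- c("# Edge-gradient recruitment analysis", "",
          sprintf("Seed: %d", report$seed),
          sprintf("Stations: %d; plots: %d; species: %d",
                  report$n_stations, report$n_plots, report$n_species), "")
  for (ix in names(report$diversity)) {
    f <- report$diversity[[ix]]
    if (is.null(f)) next
    ln <- c(ln, sprintf("## Diversity: %s", ix), "",
            "Cell means (model-adjusted):", "```",
            utils::capture.output(print(f$cell_means, row.names = FALSE)),
            "```", "", "Pairwise letters:", "```",
            utils::capture.output(print(f$letters, row.names = FALSE)),
            "```", "")
  }
  if (!is.null(report$cndd)) {
    ln <- c(ln, "## CNDD slopes (b; 1 = no density dependence)", "", "```",
            utils::capture.output(print(report$cndd$summary,
                                        row.names = FALSE)),
            "```", "",
            sprintf("Converged: %s", report$cndd$converged),
            sprintf("Species retained: %d of %d",
                    report$cndd$filter$retained, report$cndd$filter$total))
  }
  ln
}
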