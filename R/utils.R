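#' Map plot treatments to analysis cells
#'
#' The two unsprayed plots (untreated control and water-sprayed
#' control) behave interchangeably and are analysed as a single
#' "Control" cell; pesticide treatments map to themselves.
#'
#' @param treatment Character vector of treatment labels.
#' @return Character vector of cell-treatment labels.
#' @export
treatment_cell <- function(treatment) {
  ifelse(treatment %in% c("control", "water"), "Control", treatment)
}

edge_levels <- function() c("E0", "E1", "E2", "E3")

known_treatments <- function() {
  c("control", "water", "fungicide", "insecticide", "both")
}

# sum counts in a long table into a named species vector over `species`
species_counts <- function(df, value_col, species) {
  out <- stats::setNames(numeric(length(species)), species)
  if (nrow(df)) {
    agg <- tapply(df[[value_col]], df$species_id, sum)
    out[names(agg)] <- agg
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
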