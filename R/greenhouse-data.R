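#' Reference greenhouse dataset: printed treatment means
#'
#' Loads one family of the sunflower greenhouse dataset shipped with the
#' package. The shipped values are the published per-cell treatment means
#' (replicate-level raw data were not released), so each table validates
#' against a 1-replicate design; they support index computation and
#' aggregation checks, but not ANOVA, which needs replicates.
#'
#' Families and responses: `"microbial"` (Org, Act, Fun; organotrophic
#' bacteria and actinomycetes in 1e9 cfu/kg, fungi in 1e7 cfu/kg),
#' `"enzymes"` (Deh, Cat, Ure, Pac, Pal, Aryl, Glu), `"yield"` (Shoots,
#' Roots, g per pot), `"spad"` (SPAD greenness).
#'
#' @param family One of `"microbial"`, `"enzymes"`, `"yield"`, `"spad"`.
#' @return A `"measurement_table"` of cell means (replicate = 1).
#' @export
#' @examples
#' tab <- greenhouse_measurements("yield")
#' cell_means(tab, "Shoots")
greenhouse_measurements <- function(family = c("microbial", "enzymes",
                                               "yield", "spad")) {
  family <- match.arg(family)
  path <- system.file("extdata", paste0("greenhouse_", family, ".csv"),
                      package = "soilsorb", mustWork = TRUE)
  read_measurements(path, greenhouse_design(replicates = c(mean = 1L)))
}

#' Published marginal means of the greenhouse tables
#'
#' The row (per-sorbent, averaged over contaminants) and column
#' (per-contaminant, averaged over sorbents) "Average" cells as printed with
#' the dataset, used by [verify_reference_values()] to check that they
#' recompute as arithmetic means of the shipped cell values.
#'
#' @return Data.frame with columns `family`, `response`, `margin`, `level`,
#'   `printed`.
#' @export
greenhouse_marginal_means <- function() {
  utils::read.csv(system.file("extdata", "greenhouse_marginal_means.csv",
                              package = "soilsorb", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published impact percentages of the greenhouse study
#'
#' The metal and sorbent impact-factor percentages reported with the
#' dataset (IF x 100), keyed by response, contaminant, sorbent and index
#' kind.
#'
#' @return Data.frame with columns `response`, `contaminant`, `sorbent`,
#'   `index`, `printed_pct`.
#' @export
greenhouse_reference_effects <- function() {
  utils::read.csv(system.file("extdata", "greenhouse_reference_effects.csv",
                              package = "soilsorb", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Measurement units of the greenhouse responses
#'
#' @return Data.frame with columns `response`, `unit`. Units are metadata
#'   only; the package never converts between them.
#' @export
greenhouse_units <- function() {
  utils::read.csv(system.file("extdata", "greenhouse_units.csv",
                              package = "soilsorb", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
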