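#' Define the factorial layout of a metal-by-sorbent experiment
#'
#' An experiment design fixes the factor levels of the two crossed treatments
#' (soil contaminant and sorbent amendment), the replicate count of each
#' response family, and the length of the colony-observation window. The first
#' contaminant level is the uncontaminated reference and the first sorbent
#' level is the sorbent-free control; impact factors are computed against
#' these references.
#'
#' @param contaminants Character vector of contaminant levels, reference
#'   (uncontaminated) level first.
#' @param sorbents Character vector of sorbent levels, sorbent-free control
#'   first.
#' @param replicates Named integer vector of replicate counts per response
#'   family (e.g. `c(microbial = 4, enzymatic = 3, yield = 3, spad = 8)`).
#'   All counts must be at least 1; [ms_anova()] additionally requires at
#'   least 2 replicates per cell.
#' @param families Named character vector mapping response names to the
#'   families named in `replicates`. Responses absent from the map fall back
#'   to the first family.
#' @param observation_days Length of the daily colony-emergence window.
#'
#' @return An object of class `"experiment_design"`.
#' @seealso [greenhouse_design()] for the layout of the shipped greenhouse
#'   dataset.
#' @export
#' @examples
#' d <- experiment_design(c("C0", "Cu"), c("Control", "Zeolite"),
#'                        replicates = c(microbial = 4))
#' d
experiment_design <- function(contaminants, sorbents,
                              replicates = c(default = 3L),
                              families = character(),
                              observation_days = 10L) {
  contaminants <- as.character(contaminants)
  sorbents <- as.character(sorbents)
  if (length(contaminants) < 1L || anyDuplicated(contaminants))
    stop("'contaminants' must be a non-empty vector of unique labels", call. = FALSE)
  if (length(sorbents) < 1L || anyDuplicated(sorbents))
    stop("'sorbents' must be a non-empty vector of unique labels", call. = FALSE)
  replicates <- vapply(replicates, as.integer, integer(1))
  if (is.null(names(replicates)) || any(!nzchar(names(replicates))))
    stop("'replicates' must be a named vector of per-family counts", call. = FALSE)
  if (any(is.na(replicates)) || any(replicates < 1L))
    stop("replicate counts must be positive integers", call. = FALSE)
  observation_days <- as.integer(observation_days)
  if (is.na(observation_days) || observation_days < 1L)
    stop("'observation_days' must be a positive integer", call. = FALSE)
  if (length(families)) {
    families <- vapply(families, as.character, character(1))
    unknown <- setdiff(unique(families), names(replicates))
    if (length(unknown))
      stop("families map to unknown replicate families: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(contaminants = contaminants, sorbents = sorbents,
         replicates = replicates, families = families,
         observation_days = observation_days),
    class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Two-factor experiment design\n")
  cat("  contaminants:", paste(x$contaminants, collapse = ", "),
      sprintf("(reference: %s)\n", x$contaminants[1]))
  cat("  sorbents:    ", paste(x$sorbents, collapse = ", "),
      sprintf("(reference: %s)\n", x$sorbents[1]))
  cat("  replicates:  ",
      paste(sprintf("%s=%d", names(x$replicates), x$replicates), collapse = ", "),
      "\n")
  cat("  observation window:", x$observation_days, "days\n")
  invisible(x)
}

# replicate count expected for one response under a design
design_replicates <- function(design, response) {
  fam <- design$families[response]
  if (is.na(fam)) fam <- names(design$replicates)[1]
  unname(design$replicates[fam])
}

#' Layout of the sunflower greenhouse experiment
#'
#' The design of the reference greenhouse study shipped with the package:
#' four contamination levels (uncontaminated `C0`, then Cu, Ni and Zn, each
#' added at 150 mg per kg of dry soil), crossed with a sorbent-free control
#' and six sorbents, with microbial counts in 4 replicates, enzyme activities
#' in 3, pot yields in 3, SPAD greenness in 8, and a 10-day colony
#' observation window.
#'
#' @param replicates Named replicate counts per family; override to validate
#'   tables that carry cell means (1 replicate) instead of raw replicates.
#' @return An `"experiment_design"` object.
#' @export
#' @examples
#' greenhouse_design()
greenhouse_design <- function(replicates = c(microbial = 4L, enzymatic = 3L,
                                             yield = 3L, spad = 8L)) {
  families <- c(Org = "microbial", Act = "microbial", Fun = "microbial",
                Deh = "enzymatic", Cat = "enzymatic", Ure = "enzymatic",
                Pac = "enzymatic", Pal = "enzymatic", Aryl = "enzymatic",
                Glu = "enzymatic",
                Shoots = "yield", Roots = "yield", SPAD = "spad")
  families <- families[families %in% names(replicates)]
  experiment_design(
    contaminants = c("C0", "Cu", "Ni", "Zn"),
    sorbents = c("Control", "Molecular sieve", "Halloysite", "Sepiolite",
                 "Expanded clay", "Biochar", "Zeolite"),
    replicates = replicates,
    families = families,
    observation_days = 10L)
}
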